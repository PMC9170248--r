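# oplgj

Quantitative analysis of rod/cone gap junctions in the outer plexiform
layer (OPL) of the mouse retina.

Rod spherules couple to cone pedicles through small, string-like Cx36 gap
junctions at the base of the spherule. This package implements, as tested
reusable code, the analysis pipeline that turns connectomics, volume-EM
morphometry, and confocal puncta counts into an estimate of the coupling
biophysics:

- **Contact-graph connectivity** (`contact_graph()`, `convergence()`,
  `divergence()`, `coverage()`, `shared_and_exclusive()`,
  `uncontacted_fraction()`) — bipartite rod × cone adjacency with
  central-subset edge-effect handling.
- **Gap-junction morphometry** (`junction_patch()`, `measure_patch()`,
  `junction_distance()`, `summarize_distances()`,
  `per_rod_counts_and_totals()`) — the belt-like junction is summarized as
  a rectangle (plane fit, length along the first principal axis, width =
  projected area / length) plus its 3D distance to the rod synaptic
  opening.
- **Confocal puncta quantification** (`colocalize_count()`,
  `clusters_per_rod()`, `align_and_average()`, `perimeter_profile()`) —
  3D colocalized-object counting, rod-spherule alignment/averaging, and
  closed-spline perimeter linearization of per-channel intensity.
- **The coupling estimation chain** (`run_chain()`,
  `spacing_from_density()`, `propagate_product()`, `bootstrap_mean_sem()`)
  — hexagonal-packing density→spacing, length→connexon count,
  junctions/pair, maximal conductance, and channel open probability, with
  quadrature error propagation:

  d = √(2/(√3·ρ)) = 9.45 nm, L̄/d = 50.5 connexons/junction,
  3.21/1.89 = 1.70 junctions/pair → 85.9 connexons/pair,
  g_max = 85.9 × 14.3 pS ≈ 1228 pS,
  P_o = g_measured / g_max → 25.0% (dark), 2.89% (quinpirole),
  107% (spiperone).

- **A synthetic OPL generator** (`scene_config()`, `simulate_scene()`,
  `render_confocal_volume()`, `simulate_pedicle_scene()`) — cone mosaics,
  rod fields, contact graphs, junction geometry, and rendered 3-channel
  volumes with exported ground truth, so every stage is testable without
  any external data.

## Worked example

```r
library(oplgj)

chain <- run_chain(reference_inputs(), rounding = "printed")
chain
#> Rod/cone coupling estimation chain (printed rounding, quadrature propagation)
#>   connexon spacing:     9.45 ± 0.296 nm (mean ± SEM, n = 12)
#>   connexons/junction:   50.5 ± 2.6 (mean ± SEM)
#>   string estimate:      48 connexons (10 nm spacing)
#>   junctions/pair:       1.7 ± 0.105 (mean ± SEM)
#>   connexons/pair:       85.9 ± 6.91 (mean ± SEM)
#>   maximal conductance:  1228 ± 120 pS (mean ± SEM)
#>   open probability, dark:      25 ± 2.45 % (mean ± SEM)
#>   open probability, quinpirole: 2.89 ± 0.293 % (mean ± SEM)
#>   open probability, spiperone: 107 ± 10.6 % (mean ± SEM)
#>   dynamic range:        37
```

The spacing follows from hexagonal packing of the freeze-fracture plaque
density; dividing the 477 nm mean junction length by it gives ~50 channels
per junction; sharing 3.21 junctions/rod among 1.89 cones and multiplying
by the 14.3 pS unitary conductance yields the ~1228 pS morphological
maximum, against which the measured conductances become open
probabilities. The 107% ceiling case says that under D2-antagonist
saturation essentially every connexon in the string is conducting.

A synthetic scene end to end:

```r
scene <- simulate_scene(scene_config(seed = 1))
scene
#> Synthetic OPL scene: 29 cones, 870 rods, 1237 contacts, 2770 gap junctions (seed 1 )
report <- connectivity_report(scene_contact_graph(scene))
report
#> Rod/cone connectivity report
#>   edges: 1237
#>   convergence (central cones): 43.5 ± 12.29227 (mean ± SD, n = 6)
#>   divergence (all rods): 1.423475 ± 0.6186066 (mean ± SD, n = 869)
#>   divergence (central rods): 1.6 ± 0.6649895 (mean ± SD, n = 200)
#>   coverage: 1.46
#>   exclusive rods/cone: 16.66667 ± 5.46504 (mean ± SD, n = 6)
#>   uncontacted rods: 1 / 870 (0.1%)
```

Convergence lands on the published 43 rods per cone; divergence over the
central rods (1.6) runs below the published 1.89 because convex synthetic
fields under-share rods relative to real interdigitating telodendria — the
methods vignette quantifies this bias.

The numbered scripts under `analysis/` run the full study on one seed
(`OPLGJ_SEED` environment variable, default 1): `01_simulate.R` writes the
scene tables, `02_connectivity.R` the graph metrics, `03_geometry.R` the
junction morphometry, `04_confocal.R` renders a single-pedicle volume and
counts the planted Cx36 puncta back, `05_estimate.R` runs the estimation
chain. Outputs land under `results/run_seed<N>/`. `run_pipeline()` does the
same in one call with a digest manifest.

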