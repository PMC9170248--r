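---
title: "Quantifying rod/cone gap junctions: models, generators, and the estimation chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rod/cone gap junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplgj)
```

## The scientific problem

Rods and cones in the mammalian retina are electrically coupled through
small, string-like Cx36 gap junctions where cone telodendria touch the base
of rod spherules. Because each junction is a sparse string of connexons
rather than a crystalline plaque, classic plaque-area estimates of channel
number do not apply, and the physiological open probability of the channels
has been hard to pin down. This package implements the quantitative pipeline
that connects three kinds of measurement:

1. **connectivity** — a bipartite contact graph between rod spherules and
   cone pedicles (convergence, divergence, coverage, shared/exclusive rods);
2. **morphometry** — per-junction length/width from volume-EM segmentations
   and the 3D distance from each junction to the rod's synaptic opening;
3. **a biophysical estimation chain** — from connexon packing density to
   connexon counts, maximal junctional conductance, and channel open
   probability under three pharmacological conditions.

Everything runs end-to-end on synthetic scenes with exported ground truth,
so each stage is testable without any external imaging data.

## The estimation chain

The chain multiplies and divides a handful of measured quantities, each a
mean with a standard error:

- plaque density $\rho = 12{,}940 \pm 405\ \mu m^{-2}$ (freeze fracture);
- hexagonal packing gives the connexon spacing
  $d = \sqrt{2 / (\sqrt{3}\,\rho)} = 9.45$ nm;
- mean junction length $\bar L = 477 \pm 19.5$ nm, so
  $\bar L / d = 50.5$ connexons per junction;
- $3.21 \pm 0.190$ junctions per rod, shared among $1.89 \pm 0.0337$ cones,
  gives $1.70$ junctions and $85.9$ connexons per rod/cone pair;
- at $\gamma = 14.3 \pm 0.8$ pS per channel the maximal conductance is
  $g_{max} \approx 1228 \pm 120$ pS;
- measured transjunctional conductances (307 pS in darkness, 35.5 pS under
  quinpirole, 1312 pS under spiperone) divided by $g_{max}$ give open
  probabilities of 25.0%, 2.89%, and 107%.

```{r chain}
chain <- run_chain(reference_inputs(), rounding = "printed")
chain
```

### Error propagation

Relative errors are combined in quadrature,
$\mathrm{rel}_{out} = \sqrt{\sum_i \mathrm{rel}_i^2}$, ignoring exponent
magnitude; this is the convention that reproduces every printed SEM in the
source calculation to three significant figures. A textbook delta-method
mode (`propagation = "delta"`, weighting each relative error by its
exponent) is provided for comparison. The same choice appears in the
density-to-spacing step: the printed spacing SEM (0.296 nm) equals a linear
pass-through of the density's relative SEM; the delta-method value for a
$-\tfrac12$ power would be half that (0.148 nm). `spacing_err = "published"`
reproduces the published number, `"delta"` the statistical standard.

### Rounding modes

`rounding = "printed"` rounds each intermediate to the precision at which
the published tables print values — three significant figures, half away
from zero, four digits for conductances above 1000 pS — before feeding the
next step. This is required to reproduce the published 85.9 connexons per
pair: the unrounded product is 85.76, which `rounding = "full"` exposes.
The end-to-end discrepancy between modes is below 0.3% everywhere; both are
reported side by side by the pipeline. Note that ordinary `signif()` rounds
half to even and would turn $1.70 \times 50.5 = 85.85$ into 85.8; printed
tables round half up, so the package implements that convention explicitly
(`signif_half_up()`).

Open probability is deliberately **not** clipped at 100%: the spiperone
condition exceeds the morphology-derived maximum (107% ± 10.6%), which is
itself informative about the accumulated systematic error of the chain. The
dynamic range is reported as the ratio of the extreme open probabilities
(107/2.89 ≈ 37); narrative figures of "~20" or "~30" in the source
literature arise from rounding different intermediate pairs and are not
separately modeled.

## The synthetic scene generator

`scene_config()` fixes the study conditions; `simulate_scene()` draws a
scene from per-stage RNG substreams of one master seed, so any stage can be
regenerated independently and two runs with the same seed are identical.

- **Cone mosaic** — jittered hexagonal lattice at $1.56/104$ cones per
  $\mu m^2$ over a $44 \times 44\ \mu m$ region (~29 pedicles). Each cone
  gets a convex telodendrial-field polygon (convex hull of radially
  jittered points, rescaled so its area is an exact draw from
  $\mathcal N(104, 20^2)\ \mu m^2$, truncated positive). The published field
  SD of 0.2 $\mu m^2$ over 29 cones is implausibly tight for a biological
  area measurement, so the spread is freely configurable with a 20 $\mu m^2$
  default (~20% CV). With these defaults, summed field area over region
  area — the coverage factor — is 1.56 by construction.
- **Rod field** — `round(30 × n_cones)` rods, placed uniformly over the
  telodendria-covered area (rod spherules mass above and between pedicles)
  plus a 0.5% stray fraction that may land in coverage holes; these strays
  become the rare uncontacted rods. Small fractions carry morphological
  variant tags (`roof` rods sit on a pedicle footprint, `inverted`,
  `low_row`); variants only modify the contact rule for roof rods, which
  are contacted within `roof_tolerance` of the pedicle disc.
- **Contacts** — an edge (rod, cone) exists iff the rod opening lies inside
  the cone's field polygon (point-in-polygon), so re-running
  `assign_contacts()` on exported tables reproduces the stored edge list
  exactly.
- **Gap junctions** — per contacted rod, a count from a pmf on 1..6
  (a discretized normal whose latent location/scale are solved so the
  discrete mean and SD are exactly 3.21 and 1.23), partitioned across the
  rod's cones by inverse-distance multinomial. Lengths are truncated normal
  with minimum 100 nm; the latent location is calibrated (~447 nm) so the
  *realized* mean equals the configured 477 nm — naive truncation would
  inflate it to ~501 nm. Distances to the synaptic opening are log-normal
  with median 0.435 $\mu m$; the default sigma 0.837 is solved from the
  constraint that 84% of junctions fall within 1 $\mu m$. The log-normal
  shape itself is a modeling choice — the source data are only described as
  skewed with that median.
- **Rendering** — three channels (Cx36 puncta; pedicle discs plus
  telodendrial polylines with bright tips at each contact; two-lobed rod
  spherule bodies with voids at the synaptic opening and mitochondrion),
  separable Gaussian PSF blur (default $\sigma_{xy}$ 72 nm from the 170 nm
  FWHM of the emulated instrument, $\sigma_z$ 250 nm), additive Gaussian
  noise, intensities clamped non-negative. Voxels follow the 0-based
  (z, y, x) convention with physical positions at voxel centers.

### What the generator does and does not emulate

Realized connectivity statistics under the defaults (pooled over 10 seeds):
convergence ≈ 47 rods/cone (published 43.0 ± 5.40), central-rod divergence
≈ 1.7 (published 1.89), coverage ≈ 1.5, uncontacted fraction ≈ 0.1%
(published 0.4%). Two published statistics are *not* reproduced and cannot
be under this geometry: with convex fields at coverage 1.56, the mean rod
degree is pinned near 1.5–1.7 (otherwise convergence would exceed its
envelope), which caps the fraction of rods contacting two or three cones
near ~56% (published 74%) and leaves ~16 exclusive rods per central cone
(published 7.23). Real telodendrial fields interdigitate — non-convex
outlines share rods far more efficiently than convex hulls of the same
area. Passing tests therefore demonstrate correct bookkeeping and faithful
parameter recovery, not that convex-field scenes are geometrically
indistinguishable from retinal tissue.

## Morphometry choices

- Junction patches are summarized as rectangles: total-least-squares plane
  fit (SVD) to voxel centers, length = extent along the first in-plane
  principal axis plus one voxel pitch, width = projected area / length
  (the mean belt width, not the maximum transverse extent). On a curved
  quarter-circle belt the chord-based length underestimates arc length by
  well under 10% because the extreme corners dominate the extent — the test
  suite documents this bias against the analytic arc length.
- Projected area sums per-voxel silhouettes, which overcounts for patches
  thicker than one voxel along the normal; junction segmentations are
  essentially membrane-thin, so the bias is negligible there.
- Distance to the synaptic opening is centroid-to-center Euclidean, not
  geodesic along the spherule surface; the interactive slicing used for the
  published measurements is not reproducible in code, and Euclidean is.
- Patches under 3 voxels are flagged degenerate (voxel diagonal for both
  dimensions) rather than dropped.

## Confocal quantification choices

- Connectivity is 26-neighbor in 3D 8-neighbor in 2D; components come from
  the voxel-adjacency graph, cross-checked in tests against an independent
  flood-fill oracle.
- Default thresholds are per-channel Otsu with a refinement for sparse
  puncta channels: when the first pass leaves more than 10% of the volume
  above threshold (physically implausible for labeled puncta — the pass has
  merely separated noise from zero), Otsu is re-run on the supra-threshold
  voxels only. Structural channels with a balanced histogram are untouched.
  Explicit thresholds override both.
- The minimum object size defaults to the voxel volume of a sphere one PSF
  FWHM (170 nm) in diameter; smaller objects are unresolvable and treated
  as noise.
- Puncta are assigned to the rod with the nearest opening center; a punctum
  whose two nearest rods differ by less than `ambiguity_radius` (default
  0.3 µm) is excluded as ambiguous, mirroring the manual exclusion of
  spherules too crowded to attribute.
- Spherule crops are aligned by intensity centroid and rotated so the
  annotated opening sits at 6 o'clock; the perimeter profile fits a
  periodic cubic spline through arc-equidistant control points of the
  structural channel's iso-contour (default level: half maximum), samples
  `n_samples` equally spaced arc positions clockwise from the 6 o'clock
  origin, and averages each channel over 5 bilinear samples across a
  272 nm band. On a circular ring the band integral equals the mask
  integral exactly (inner/outer curvature corrections cancel), which the
  tests exploit as a conservation check.

## Problem sizes and determinism

Tests and the analysis scripts use a 44 × 44 µm scene (~29 cones, ~870
rods, ~2500 junctions) for table-level statistics, 12 µm mini-scenes for
oracle comparisons, and 17 µm single-pedicle renders at 60 nm xy voxels for
imaging recovery; these sizes keep a full run on one CPU in a few minutes
while leaving every sample large enough for the stated tolerances. All
randomness flows from one master seed through fixed per-stage substreams
(`stage_seed()`), and the pipeline manifest records md5 digests of every
output so reruns are verifiably identical.

## Known limitations

- Convex telodendrial fields under-share rods (see above); blue-cone
  pathway specifics are limited to an `is_blue` flag.
- The renderer emulates marker distributions, PSF, and noise — not optical
  sectioning artifacts, bleed-through, or depth-dependent attenuation, so
  image-based recovery tests certify the quantification code, not
  robustness to every real-world aberration.
- The estimation chain consumes printed summary statistics as inputs; it
  does not re-fit the underlying electrophysiological recordings.
- Appendix-level propagation details beyond the printed SEMs are
  reverse-engineered; the quadrature convention reproduces all of them, but
  that is a consistency argument, not a derivation.
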