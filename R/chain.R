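#' Connexon spacing from plaque packing density
#'
#' Under a hexagonal-packing model, particles at areal density `rho` have
#' center-to-center spacing `d = sqrt(2 / (sqrt(3) * rho))`. With the
#' freeze-fracture plaque density of Cx36 (12,940 per um^2) this gives the
#' 9.45 nm spacing used to convert gap-junction string length into a connexon
#' count.
#'
#' Two uncertainty conventions are offered. `"published"` reproduces the printed convention: it passes the density's
#' relative SEM through unchanged (the convention behind the printed
#' 0.296 nm); `"delta"` applies the first-order delta method for the -1/2
#' power, giving half that relative error.
#'
#' @param rho a [quantity()] in `1/um^2` (or a bare number).
#' @param err_mode `"published"` or `"delta"`.
#' @return A [quantity()] in nm.
#' @examples
#' spacing_from_density(quantity(12940, 405, "SEM", n = 12, units = "1/um^2"))
#' @export
spacing_from_density <- function(rho, err_mode = c("published", "delta")) {
  err_mode <- match.arg(err_mode)
  if (!inherits(rho, "quantity")) rho <- quantity(rho, units = "1/um^2")
  if (rho$value <= 0) stop("plaque density must be positive")
  rho_nm2 <- rho$value * 1e-6            # 1/um^2 -> 1/nm^2
  d <- sqrt(2 / (sqrt(3) * rho_nm2))
  rel <- rel_err(rho) * switch(err_mode, published = 1, delta = 0.5)
  quantity(d, d * rel, if (rel > 0) rho$err_kind else "none",
           n = rho$n, units = "nm")
}

#' Packing density from connexon spacing
#'
#' Inverse of [spacing_from_density()]: `rho = 2 / (sqrt(3) * d^2)`.
#'
#' @param d_nm spacing in nm.
#' @return density in `1/um^2`.
#' @export
density_from_spacing <- function(d_nm) {
  stopifnot(d_nm > 0)
  2 / (sqrt(3) * d_nm^2) * 1e6
}

#' Reference inputs for the coupling estimation chain
#'
#' The published morphological and physiological constants consumed by
#' [run_chain()]: freeze-fracture plaque density, mean gap-junction length,
#' junctions per rod spherule, rod-to-cone divergence, Cx36 unitary
#' conductance, measured transjunctional conductances in darkness, under the
#' D2 agonist quinpirole, and under the D2 antagonist spiperone, and the 10 nm
#' string spacing from earlier freeze-fracture work. All uncertainties are
#' SEMs on the printed scale.
#'
#' @return Named list of [quantity()] objects.
#' @export
reference_inputs <- function() {
  list(
    plaque_density      = quantity(12940, 405,   "SEM", n = 12,  units = "1/um^2"),
    gj_length           = quantity(477,   19.5,  "SEM", n = 135, units = "nm"),
    gj_per_rod          = quantity(3.21,  0.190, "SEM", n = 42,  units = ""),
    divergence          = quantity(1.89,  0.0337,"SEM", n = 361, units = ""),
    unitary_conductance = quantity(14.3,  0.8,   "SEM", n = 92,  units = "pS"),
    g_dark              = quantity(307,   2.31,  "SEM", units = "pS"),
    g_quinpirole        = quantity(35.5,  0.968, "SEM", n = 500, units = "pS"),
    g_spiperone         = quantity(1312,  22.8,  "SEM", n = 500, units = "pS"),
    string_spacing      = quantity(10, units = "nm")
  )
}

#' Reference connectivity and cluster-count constants
#'
#' Published summary statistics used for juxtaposition in reports and for the
#' per-cone gap-junction consistency identity: convergence (rods per cone),
#' Cx36 clusters per cone pedicle and per rod spherule, divergence, coverage,
#' telodendrial field area, and the uncontacted-rod tally.
#'
#' @return Named list of [quantity()] objects plus plain counts.
#' @export
reference_connectivity <- function() {
  list(
    convergence          = quantity(43.0, 5.40, "SD", n = 29, units = ""),
    clusters_per_pedicle = quantity(51.4, 8.88, "SD", n = 18, units = ""),
    clusters_per_rod     = quantity(2.48, 1.01, "SD", n = 260, units = ""),
    divergence           = quantity(1.89, 0.0337, "SEM", n = 361, units = ""),
    coverage             = quantity(1.56, units = ""),
    field_area           = quantity(104, units = "um^2"),
    exclusive_per_cone   = quantity(7.23, 3.38, "SD", n = 13, units = ""),
    shared_per_pair      = quantity(6.23, 4.67, "SD", n = 79, units = ""),
    gj_length_sd         = quantity(477, 227, "SD", n = 135, units = "nm"),
    total_length_per_rod = quantity(1.53, 0.439, "SD", n = 42, units = "um"),
    distance_median_um   = 0.435,
    frac_within_1um      = 0.84,
    frac_within_2um      = 0.94,
    uncontacted          = c(k = 3, n = 811)
  )
}

#' Per-cone gap-junction consistency identity
#'
#' Cross-checks the confocal cluster counts against the EM connectivity:
#' junctions per cone pedicle = convergence x clusters per rod / divergence
#' (43 x 2.48 / 1.89 = 56.4), with quadrature-propagated relative uncertainty.
#'
#' @param convergence,clusters_per_rod,divergence [quantity()] objects or bare
#'   numbers.
#' @param mode propagation mode, see [propagate_product()].
#' @return A [quantity()], junctions per cone pedicle.
#' @export
gj_per_cone_identity <- function(convergence, clusters_per_rod, divergence,
                                 mode = c("quadrature", "delta")) {
  mode <- match.arg(mode)
  as_q <- function(x) if (inherits(x, "quantity")) x else quantity(x)
  divergence <- as_q(divergence)
  if (divergence$value == 0) stop("divergence must be non-zero")
  propagate_product(list(as_q(convergence), as_q(clusters_per_rod), divergence),
                    c(1, 1, -1), mode = mode, units = "")
}

#' Run the rod/cone coupling estimation chain
#'
#' Executes the full estimation chain from connexon packing density to channel
#' open probability:
#' \enumerate{
#'   \item spacing `d` from plaque density (hexagonal packing);
#'   \item connexons per gap junction = mean junction length / `d`;
#'   \item gap junctions per rod/cone pair = junctions per rod / divergence;
#'   \item connexons per pair = junctions per pair x connexons per junction;
#'   \item maximal conductance `g_max` = connexons per pair x unitary
#'     conductance;
#'   \item open probability per pharmacological condition = measured
#'     conductance / `g_max` x 100%.
#' }
#' In `rounding = "printed"` each intermediate is rounded to the precision at
#' which the source tables print values (3 significant figures, half away from
#' zero; 4 for conductances above 1000 pS) before feeding the next step, which
#' reproduces the printed numbers exactly. `rounding = "full"` carries full
#' precision and documents the small (<0.3%) sensitivity of the chain to
#' intermediate rounding.
#'
#' @param inputs named list of [quantity()] objects as from
#'   [reference_inputs()]; all nine symbols must be present.
#' @param rounding `"printed"` or `"full"`.
#' @param propagation `"quadrature"` or `"delta"`, see [propagate_product()].
#' @param spacing_err `"published"` or `"delta"`, see [spacing_from_density()].
#' @return An object of class `estimation_chain`: spacing, connexons_per_gj,
#'   string_connexons, gj_per_pair, connexons_per_pair, g_max,
#'   open_probability (named list over conditions, percent), dynamic_range,
#'   and the modes used.
#' @examples
#' ch <- run_chain(reference_inputs(), rounding = "printed")
#' ch$g_max$value         # 1228 pS
#' ch$open_probability$dark$value   # 25.0 %
#' @export
run_chain <- function(inputs = reference_inputs(),
                      rounding = c("printed", "full"),
                      propagation = c("quadrature", "delta"),
                      spacing_err = c("published", "delta")) {
  rounding <- match.arg(rounding)
  propagation <- match.arg(propagation)
  spacing_err <- match.arg(spacing_err)
  required <- c("plaque_density", "gj_length", "gj_per_rod", "divergence",
                "unitary_conductance", "g_dark", "g_quinpirole", "g_spiperone",
                "string_spacing")
  missing <- setdiff(required, names(inputs))
  if (length(missing))
    stop("missing chain input(s): ", paste(missing, collapse = ", "))
  rnd <- if (rounding == "printed") round_printed else identity

  spacing <- rnd(spacing_from_density(inputs$plaque_density, spacing_err))
  connexons_per_gj <- rnd(propagate_product(
    list(inputs$gj_length, spacing), c(1, -1), mode = propagation))
  # coarse estimate from the historical 10 nm string spacing: 477/10 ~ 48
  string_raw <- inputs$gj_length$value / inputs$string_spacing$value
  string_connexons <- if (rounding == "printed") round(string_raw) else string_raw
  gj_per_pair <- rnd(propagate_product(
    list(inputs$gj_per_rod, inputs$divergence), c(1, -1), mode = propagation))
  connexons_per_pair <- rnd(propagate_product(
    list(gj_per_pair, connexons_per_gj), c(1, 1), mode = propagation))
  g_max <- rnd(propagate_product(
    list(connexons_per_pair, inputs$unitary_conductance), c(1, 1),
    mode = propagation))
  if (g_max$value <= 0) stop("maximal conductance must be positive")

  po <- function(g) {
    q <- propagate_product(list(g, g_max), c(1, -1), mode = propagation)
    rnd(quantity(q$value * 100, q$err * 100, q$err_kind, n = q$n, units = "%"))
  }
  open_probability <- list(
    dark       = po(inputs$g_dark),
    quinpirole = po(inputs$g_quinpirole),
    spiperone  = po(inputs$g_spiperone)
  )
  dynamic_range <- open_probability$spiperone$value /
    open_probability$quinpirole$value

  structure(
    list(spacing = spacing, connexons_per_gj = connexons_per_gj,
         string_connexons = string_connexons, gj_per_pair = gj_per_pair,
         connexons_per_pair = connexons_per_pair, g_max = g_max,
         open_probability = open_probability, dynamic_range = dynamic_range,
         rounding = rounding, propagation = propagation,
         spacing_err = spacing_err),
    class = "estimation_chain"
  )
}

#' @export
print.estimation_chain <- function(x, ...) {
  cat("Rod/cone coupling estimation chain (", x$rounding, " rounding, ",
      x$propagation, " propagation)\n", sep = "")
  cat("  connexon spacing:    ", format_quantity(x$spacing), "\n")
  cat("  connexons/junction:  ", format_quantity(x$connexons_per_gj), "\n")
  cat("  string estimate:     ", format(x$string_connexons),
      "connexons (10 nm spacing)\n")
  cat("  junctions/pair:      ", format_quantity(x$gj_per_pair), "\n")
  cat("  connexons/pair:      ", format_quantity(x$connexons_per_pair), "\n")
  cat("  maximal conductance: ", format_quantity(x$g_max), "\n")
  for (cond in names(x$open_probability))
    cat(sprintf("  open probability, %-10s %s\n", paste0(cond, ":"),
                format_quantity(x$open_probability[[cond]])))
  cat("  dynamic range:       ", format(signif(x$dynamic_range, 3)), "\n")
  invisible(x)
}

#' Bootstrap mean and its standard error
#'
#' Draws `B` resamples with replacement, returns the mean of resample means as
#' the value and their standard deviation as a SEM-type uncertainty.
#' Deterministic given `seed`.
#'
#' @param samples numeric vector, length >= 2.
#' @param B number of bootstrap resamples (default 500).
#' @param seed integer RNG seed.
#' @param units unit string for the result.
#' @return A [quantity()] with `err_kind = "SEM"` and `n = length(samples)`.
#' @export
bootstrap_mean_sem <- function(samples, B = 500, seed = 1, units = "") {
  if (length(samples) < 2) stop("need at least 2 samples to bootstrap")
  stopifnot(B >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(samples)
  means <- vapply(seq_len(B),
                  function(i) mean(samples[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  err <- stats::sd(means)
  quantity(mean(means), err, if (err > 0) "SEM" else "none",
           n = n, units = units)
}

#' Recover a planted open probability from simulated conductances
#'
#' Closes the loop for parameter-recovery testing: conductance samples are
#' drawn around `po * g_max`, bootstrapped to a mean with SEM, and divided by
#' the chain's maximal conductance, giving a recovered open probability in
#' percent with propagated uncertainty.
#'
#' @param po planted open probability in (0, 1.2].
#' @param g_max maximal conductance [quantity()] (pS), e.g. from [run_chain()].
#' @param n_cells number of simulated pair recordings.
#' @param noise_sd recording noise SD in pS.
#' @param B bootstrap resamples.
#' @param seed integer RNG seed.
#' @return A [quantity()] in percent.
#' @export
recover_open_probability <- function(po, g_max, n_cells = 50, noise_sd = 10,
                                     B = 500, seed = 1) {
  stopifnot(po > 0, po <= 1.2, inherits(g_max, "quantity"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- stats::rnorm(n_cells, mean = po * g_max$value, sd = noise_sd)
  g_hat <- bootstrap_mean_sem(g, B = B, seed = seed + 1L, units = "pS")
  q <- propagate_product(list(g_hat, g_max), c(1, -1))
  quantity(q$value * 100, q$err * 100, q$err_kind, n = n_cells, units = "%")
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read estimation-chain inputs from a YAML file
#'
#' Each entry maps a chain symbol to `value`, `err`, `err_kind`, `n`, and
#' `units`; missing fields default to an errorless dimensionless quantity.
#' Symbols not present fall back to the bundled published constants, so a
#' partial file overrides only what it names.
#'
#' @param path YAML file path.
#' @param defaults base input set (default [reference_inputs()]).
#' @return Named list of [quantity()] objects suitable for [run_chain()].
#' @export
read_chain_inputs <- function(path, defaults = reference_inputs()) {
  raw <- yaml::read_yaml(path)
  for (nm in names(raw)) {
    f <- raw[[nm]]
    defaults[[nm]] <- quantity(
      value = as.numeric(f$value),
      err = if (is.null(f$err)) 0 else as.numeric(f$err),
      err_kind = if (is.null(f$err_kind)) if (is.null(f$err)) "none" else "SEM"
                 else f$err_kind,
      n = if (is.null(f$n)) NA_integer_ else as.integer(f$n),
      units = if (is.null(f$units)) "" else f$units)
  }
  defaults
}
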