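#' Configuration for a synthetic outer-plexiform-layer scene
#'
#' Collects every tunable of the synthetic generator with defaults emulating
#' the quantified mouse OPL patch: a ~44 x 44 um region holding ~29 cone
#' pedicles (coverage 1.56 with 104 um^2 telodendrial fields), a 30:1
#' rod:cone ratio, 1-6 gap junctions per rod with mean 3.21 and SD 1.23,
#' junction lengths 477 +/- 227 nm (min 100 nm), constant 120 nm width, and
#' junction-to-opening distances log-normal with median 0.435 um and sigma
#' 0.837 (so 84% fall within 1 um). Imaging defaults mirror Airyscan
#' acquisition: 40 nm xy pixels, 150 nm optical sections, 170 nm FWHM PSF
#' (sigma_xy ~ 72 nm).
#'
#' @param region_width,region_height region size, um.
#' @param cone_density cones per um^2; the default `1.56/104` makes expected
#'   coverage 1.56 by construction.
#' @param rod_cone_ratio rods per cone (default 30).
#' @param blue_fraction fraction of cones flagged blue, in `[0,1]`.
#' @param field_area_mean,field_area_sd telodendrial field area, um^2.
#' @param pedicle_radius cone pedicle footprint radius, um.
#' @param gj_per_rod_pmf probability vector over junction counts 1..6; default
#'   from [discretized_count_pmf()] matched to mean 3.21, SD 1.23.
#' @param gj_length_mean,gj_length_sd,gj_length_min junction length
#'   distribution, nm (truncated normal; the latent location is calibrated so
#'   the truncated mean equals `gj_length_mean`).
#' @param gj_width constant junction width, nm.
#' @param distance_log_median,distance_log_sigma log-normal junction-to-opening
#'   distance, um (median) and log-scale sigma.
#' @param opening_radius_mean,opening_radius_sd synaptic opening radius, um.
#' @param variant_fractions named fractions for rod variants
#'   `roof`, `inverted`, `low_row`; remainder is `standard`.
#' @param roof_tolerance contact tolerance for roof-variant rods, um.
#' @param voxel_xy,voxel_z voxel size, nm.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, nm.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param seed integer master seed; per-stage substreams are derived from it.
#' @return A validated object of class `scene_config`.
#' @export
scene_config <- function(region_width = 44, region_height = 44,
                         cone_density = 1.56 / 104,
                         rod_cone_ratio = 30,
                         blue_fraction = 0.04,
                         field_area_mean = 104, field_area_sd = 20,
                         pedicle_radius = 2.5,
                         gj_per_rod_pmf = discretized_count_pmf(3.21, 1.23),
                         gj_length_mean = 477, gj_length_sd = 227,
                         gj_length_min = 100, gj_width = 120,
                         distance_log_median = 0.435,
                         distance_log_sigma = 0.837,
                         opening_radius_mean = 0.138,
                         opening_radius_sd = 0.121,
                         variant_fractions = c(roof = 0.05, inverted = 0.03,
                                               low_row = 0.02),
                         roof_tolerance = 0.5,
                         voxel_xy = 40, voxel_z = 150,
                         psf_sigma_xy = 72, psf_sigma_z = 250,
                         noise_sd = 0.01,
                         seed = 1L) {
  cfg <- list(
    region_width = region_width, region_height = region_height,
    cone_density = cone_density, rod_cone_ratio = rod_cone_ratio,
    blue_fraction = blue_fraction,
    field_area_mean = field_area_mean, field_area_sd = field_area_sd,
    pedicle_radius = pedicle_radius,
    gj_per_rod_pmf = gj_per_rod_pmf,
    gj_length_mean = gj_length_mean, gj_length_sd = gj_length_sd,
    gj_length_min = gj_length_min, gj_width = gj_width,
    distance_log_median = distance_log_median,
    distance_log_sigma = distance_log_sigma,
    opening_radius_mean = opening_radius_mean,
    opening_radius_sd = opening_radius_sd,
    variant_fractions = variant_fractions,
    roof_tolerance = roof_tolerance,
    voxel_xy = voxel_xy, voxel_z = voxel_z,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  pos <- c("region_width", "region_height", "cone_density", "rod_cone_ratio",
           "field_area_mean", "field_area_sd", "pedicle_radius",
           "gj_length_mean", "gj_length_sd", "gj_width",
           "distance_log_median", "distance_log_sigma",
           "opening_radius_mean", "voxel_xy", "voxel_z",
           "psf_sigma_xy", "psf_sigma_z")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("scene_config: '", nm, "' must be a positive scalar")
  }
  if (cfg$gj_length_min <= 0 || cfg$gj_length_min >= cfg$gj_length_mean)
    stop("scene_config: gj_length_min must be in (0, gj_length_mean)")
  if (cfg$blue_fraction < 0 || cfg$blue_fraction > 1)
    stop("scene_config: blue_fraction must be in [0,1]")
  pmf <- cfg$gj_per_rod_pmf
  if (length(pmf) != 6 || any(pmf < 0) || abs(sum(pmf) - 1) > 1e-9)
    stop("scene_config: gj_per_rod_pmf must be a length-6 probability vector summing to 1")
  vf <- cfg$variant_fractions
  if (!all(c("roof", "inverted", "low_row") %in% names(vf)) ||
      any(vf < 0) || sum(vf) > 1)
    stop("scene_config: variant_fractions must name roof/inverted/low_row and sum to <= 1")
  if (cfg$noise_sd < 0) stop("scene_config: noise_sd must be >= 0")
  invisible(cfg)
}

#' Discretized truncated-normal count pmf
#'
#' Builds a probability vector over integer counts (default 1..6) by
#' discretizing a normal distribution whose latent location and scale are
#' solved numerically so that the *discrete* pmf has exactly the requested
#' mean and SD. Used for the gap-junctions-per-rod distribution (mean 3.21,
#' SD 1.23, range 1-6) and the Cx36-clusters-per-rod distribution (mean 2.48,
#' SD 1.01).
#'
#' @param mean,sd target mean and SD of the discrete distribution.
#' @param support integer support vector (default `1:6`).
#' @return Probability vector named by `support`.
#' @examples
#' p <- discretized_count_pmf(3.21, 1.23)
#' sum(p * (1:6))   # 3.21
#' @export
discretized_count_pmf <- function(mean, sd, support = 1:6) {
  stopifnot(sd > 0, mean > min(support), mean < max(support))
  pmf_of <- function(mu, sigma) {
    p <- stats::dnorm(support, mu, sigma)
    p / sum(p)
  }
  obj <- function(par) {
    p <- pmf_of(par[1], exp(par[2]))
    m <- sum(p * support)
    s <- sqrt(sum(p * support^2) - m^2)
    (m - mean)^2 + (s - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  p <- pmf_of(fit$par[1], exp(fit$par[2]))
  names(p) <- support
  p
}

#' Derive a per-stage RNG substream seed
#'
#' Stages of the generator draw from independent substreams derived from the
#' single master seed, so any stage can be regenerated without replaying the
#' ones before it. The derived seed stays below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage name, one of the known generator stages.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c(cones = 1L, rods = 2L, contacts = 3L, gapjunctions = 4L,
              puncta = 5L, render = 6L, chain = 7L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  as.integer((abs(as.integer(seed)) %% 99991L) * 20011L + stages[[stage]])
}
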