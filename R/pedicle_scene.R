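#' Build a single-pedicle scene with a planted punctum budget
#'
#' Emulates the single-labeled-cone experiment used to count Cx36 clusters per
#' pedicle: one cone at the region center, rods on a jittered grid around it,
#' and a known number of planted Cx36 puncta (one or more per rod) with a
#' minimum mutual separation so rendered puncta stay resolvable. Counts per
#' rod may be supplied directly (e.g. draws from
#' `discretized_count_pmf(2.48, 1.01)`) or a total punctum budget split one
#' per rod (the per-pedicle counting scenario, default 51).
#'
#' @param n_puncta total puncta when `counts` is `NULL` (one rod each).
#' @param counts optional integer vector of puncta per rod.
#' @param seed integer seed.
#' @param region region side, um.
#' @param rod_spacing rod grid spacing, um.
#' @param min_sep_xy minimum xy separation between puncta, um.
#' @param config a [scene_config()] supplying imaging parameters; its seed is
#'   overridden by `seed`.
#' @return An `opl_scene` (renderable with [render_confocal_volume()]).
#' @export
simulate_pedicle_scene <- function(n_puncta = 51, counts = NULL, seed = 1,
                                   region = 17, rod_spacing = 1.8,
                                   min_sep_xy = 0.5,
                                   config = scene_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, "puncta"))
  if (is.null(counts)) counts <- rep(1L, n_puncta)
  n_rods <- length(counts)

  # jittered rod grid, shuffled, nearest-to-center first
  gx <- seq(1.2, region - 1.2, by = rod_spacing)
  gpts <- as.matrix(expand.grid(x = gx, y = gx))
  if (nrow(gpts) < n_rods)
    stop("region too small for ", n_rods, " rods at spacing ", rod_spacing)
  gpts <- gpts + matrix(stats::runif(length(gpts), -0.25, 0.25),
                        ncol = 2)
  ctr <- region / 2
  gpts <- gpts[order((gpts[, 1] - ctr)^2 + (gpts[, 2] - ctr)^2), ,
               drop = FALSE][seq_len(n_rods), , drop = FALSE]
  rods <- data.frame(id = sprintf("r%04d", seq_len(n_rods)),
                     x_um = gpts[, 1], y_um = gpts[, 2],
                     z_um = stats::runif(n_rods, 1.6, 2.2),
                     opening_radius_um = 0.138, variant = "standard",
                     stringsAsFactors = FALSE)

  cones <- data.frame(id = "c001", x_um = ctr, y_um = ctr, is_blue = FALSE,
                      area_um2 = region^2, pedicle_radius_um = 2.5,
                      stringsAsFactors = FALSE)
  sq <- cbind(c(0, region, region, 0), c(0, 0, region, region))
  attr(cones, "polygons") <- list(c001 = sq)
  attr(cones, "region") <- c(width = region, height = region)
  class(cones) <- c("cone_mosaic", "data.frame")
  contacts <- data.frame(rod_id = rods$id, cone_id = "c001",
                         stringsAsFactors = FALSE)

  # place puncta near each rod opening, enforcing global xy separation
  placed <- matrix(numeric(0), ncol = 3)
  pun <- list()
  for (i in seq_len(n_rods)) {
    for (k in seq_len(counts[i])) {
      for (try in 1:200) {
        d <- min(0.6, max(0.15, stats::rlnorm(1, log(0.35), 0.4)))
        ang <- stats::runif(1, 0, 2 * pi)
        p <- c(rods$x_um[i] + d * cos(ang), rods$y_um[i] + d * sin(ang),
               rods$z_um[i] - stats::runif(1, 0.05, 0.2))
        if (p[1] < 0.5 || p[1] > region - 0.5 ||
            p[2] < 0.5 || p[2] > region - 0.5) next
        if (nrow(placed) == 0 ||
            min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) >=
              min_sep_xy^2) break
      }
      placed <- rbind(placed, p)
      pun[[length(pun) + 1]] <- data.frame(
        rod_id = rods$id[i], cone_id = "c001",
        x_um = p[1], y_um = p[2], z_um = p[3],
        distance_um = sqrt(sum((p - c(rods$x_um[i], rods$y_um[i],
                                      rods$z_um[i]))^2)),
        stringsAsFactors = FALSE)
    }
  }
  pun <- do.call(rbind, pun)
  gj <- data.frame(id = sprintf("gj%05d", seq_len(nrow(pun))),
                   rod_id = pun$rod_id, cone_id = pun$cone_id,
                   length_nm = config$gj_length_mean,
                   width_nm = config$gj_width,
                   distance_um = pun$distance_um, stringsAsFactors = FALSE)
  puncta <- data.frame(gj_id = gj$id, rod_id = pun$rod_id,
                       cone_id = pun$cone_id, x_um = pun$x_um,
                       y_um = pun$y_um, z_um = pun$z_um,
                       stringsAsFactors = FALSE)

  cfg <- config
  cfg$region_width <- region
  cfg$region_height <- region
  cfg$seed <- as.integer(seed)
  structure(list(config = cfg, cones = cones, rods = rods,
                 contacts = contacts, gap_junctions = gj,
                 planted_puncta = puncta),
            class = "opl_scene")
}
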