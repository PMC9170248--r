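#' Generate a cone-pedicle mosaic with telodendrial fields
#'
#' Places cone pedicles on a jittered hexagonal lattice at the configured
#' density and gives each a convex telodendrial-field polygon (convex hull of
#' radially jittered points around the pedicle center, rescaled so its area is
#' an exact draw from the configured area distribution, truncated positive).
#' A fraction `blue_fraction` of cones is flagged blue. Deterministic given
#' `config$seed`.
#'
#' @param config a [scene_config()].
#' @return A data.frame with columns `id`, `x_um`, `y_um`, `is_blue`,
#'   `area_um2`, `pedicle_radius_um`, and an attribute `polygons` (named list
#'   of n x 2 vertex matrices). Class `cone_mosaic`.
#' @export
make_cone_mosaic <- function(config) {
  validate_scene_config(config)
  W <- config$region_width; H <- config$region_height
  expected <- W * H * config$cone_density
  if (expected < 1)
    stop("region too small to hold >= 1 cone at this cone_density ",
         "(expected count ", signif(expected, 3),
         "); increase region_width/region_height or cone_density")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "cones"))

  # hexagonal lattice with the requested areal density
  a <- sqrt(2 / (sqrt(3) * config$cone_density))
  rowh <- a * sqrt(3) / 2
  ys <- seq(rowh / 2, H, by = rowh)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) a / 2 else 0
    xs <- seq(a / 2 + off, W, by = a)
    cbind(xs, ys[i])
  }))
  jit <- matrix(stats::rnorm(length(pts), 0, 0.12 * a), ncol = 2)
  pts <- pts + jit
  keep <- pts[, 1] >= 0 & pts[, 1] <= W & pts[, 2] >= 0 & pts[, 2] <= H
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 1)
    stop("region too small to hold >= 1 cone after lattice jitter; ",
         "increase region_width/region_height or cone_density")

  areas <- rtruncnorm_lower(n, config$field_area_mean, config$field_area_sd,
                            lower = 1e-6)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    k <- 14
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- 1 + stats::runif(k, -0.25, 0.25)
    ring <- cbind(cos(ang) * rad, sin(ang) * rad)
    hull <- ring[grDevices::chull(ring), , drop = FALSE]
    sc <- sqrt(areas[i] / polygon_area(hull))
    poly <- hull * sc
    polys[[i]] <- sweep(poly, 2, pts[i, ], "+")
  }
  is_blue <- stats::runif(n) < config$blue_fraction
  ids <- sprintf("c%03d", seq_len(n))
  names(polys) <- ids
  cones <- data.frame(id = ids, x_um = pts[, 1], y_um = pts[, 2],
                      is_blue = is_blue, area_um2 = areas,
                      pedicle_radius_um = config$pedicle_radius,
                      stringsAsFactors = FALSE)
  attr(cones, "polygons") <- polys
  attr(cones, "region") <- c(width = W, height = H)
  class(cones) <- c("cone_mosaic", "data.frame")
  cones
}

#' Telodendrial-field polygons of a cone mosaic
#' @param cones a `cone_mosaic` from [make_cone_mosaic()].
#' @return Named list of n x 2 vertex matrices.
#' @export
cone_polygons <- function(cones) attr(cones, "polygons")

#' Generate the rod-spherule field over a cone mosaic
#'
#' Rod count is `round(rod_cone_ratio * n_cones)`. Rod synaptic-opening
#' centers are scattered uniformly in xy over the region (rod spherules sit
#' above and between the pedicles) with depth z drawn uniformly in the
#' spherule band above the pedicle layer. Small configurable fractions are
#' tagged with the morphological variants seen in volume EM (`roof` rods
#' sitting directly on a pedicle, `inverted` spherules, `low_row` spherules
#' next to the pedicle layer); the remainder are `standard`.
#'
#' @param config a [scene_config()].
#' @param cones a `cone_mosaic`.
#' @return data.frame `id`, `x_um`, `y_um`, `z_um`, `opening_radius_um`,
#'   `variant`.
#' @export
make_rod_field <- function(config, cones) {
  validate_scene_config(config)
  if (nrow(cones) == 0) stop("cones must be non-empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "rods"))
  n <- round(config$rod_cone_ratio * nrow(cones))
  W <- config$region_width; H <- config$region_height
  # rod spherules mass above and between the pedicles, i.e. over the
  # telodendria-covered neuropil; a small stray fraction lands anywhere
  # (these become the rare rods without cone contacts)
  polys <- cone_polygons(cones)
  stray <- 0.005
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    m <- max(1000L, 3L * (n - length(x)))
    cx <- stats::runif(m, 0, W); cy <- stats::runif(m, 0, H)
    covered <- rep(FALSE, m)
    for (p in polys)
      covered <- covered | points_in_polygon(cx, cy, p)
    keep <- covered | stats::runif(m) < stray
    x <- c(x, cx[keep]); y <- c(y, cy[keep])
  }
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  vf <- config$variant_fractions
  variant <- sample(c("roof", "inverted", "low_row", "standard"), n,
                    replace = TRUE,
                    prob = c(vf[["roof"]], vf[["inverted"]], vf[["low_row"]],
                             1 - sum(vf)))
  # roof rods sit on top of a pedicle
  nroof <- sum(variant == "roof")
  if (nroof > 0) {
    ci <- sample.int(nrow(cones), nroof, replace = TRUE)
    ang <- stats::runif(nroof, 0, 2 * pi)
    rr <- cones$pedicle_radius_um[ci] * sqrt(stats::runif(nroof))
    x[variant == "roof"] <- pmin(pmax(cones$x_um[ci] + rr * cos(ang), 0), W)
    y[variant == "roof"] <- pmin(pmax(cones$y_um[ci] + rr * sin(ang), 0), H)
  }
  # depth band: standard/inverted spherules 1.2-2.8 um above the pedicle
  # plane, low-row ~0.8 um, roof rods sit at the pedicle upper surface
  z <- stats::runif(n, 1.2, 2.8)
  z[variant == "low_row"] <- stats::runif(sum(variant == "low_row"), 0.6, 1.0)
  z[variant == "roof"] <- stats::runif(sum(variant == "roof"), 0.9, 1.3)
  r <- rtruncnorm_lower(n, config$opening_radius_mean,
                        config$opening_radius_sd, lower = 0.03)
  data.frame(id = sprintf("r%04d", seq_len(n)), x_um = x, y_um = y, z_um = z,
             opening_radius_um = r, variant = variant,
             stringsAsFactors = FALSE)
}

#' Assign rod/cone contacts
#'
#' An edge (rod, cone) exists iff the rod's opening xy-position lies inside
#' the cone's telodendrial-field polygon; `roof`-variant rods are additionally
#' contacted by a cone whose pedicle footprint (disc of `pedicle_radius_um`)
#' passes within `roof_tolerance` of the rod. Every rod inside at least one
#' field is therefore contacted.
#'
#' @param cones a `cone_mosaic`.
#' @param rods a rod data.frame from [make_rod_field()].
#' @param roof_tolerance tolerance in um for roof-variant contacts.
#' @return data.frame with columns `rod_id`, `cone_id` (no duplicates).
#' @export
assign_contacts <- function(cones, rods, roof_tolerance = 0.5) {
  polys <- cone_polygons(cones)
  edges <- vector("list", nrow(cones))
  for (i in seq_len(nrow(cones))) {
    cid <- cones$id[i]
    poly <- polys[[cid]]
    if (!polygon_is_simple(poly))
      stop("invalid (self-intersecting) field polygon for cone ", cid)
    inside <- points_in_polygon(rods$x_um, rods$y_um, poly)
    hit <- rods$id[inside]
    roof <- rods$variant == "roof" &
      sqrt((rods$x_um - cones$x_um[i])^2 + (rods$y_um - cones$y_um[i])^2) <=
        cones$pedicle_radius_um[i] + roof_tolerance
    hit <- union(hit, rods$id[roof])
    if (length(hit))
      edges[[i]] <- data.frame(rod_id = hit, cone_id = cid,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  if (is.null(out))
    out <- data.frame(rod_id = character(0), cone_id = character(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$rod_id, out$cone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample gap-junction records for contacted rods
#'
#' Per contacted rod, a total junction count is drawn from the configured pmf
#' over 1..6 and partitioned across that rod's incident cones (multinomial
#' with probabilities proportional to inverse distance to each pedicle
#' center). Junction lengths are truncated-normal (latent location calibrated
#' so the realized mean equals `gj_length_mean`), widths constant, and
#' distances to the synaptic-opening center log-normal with the configured
#' median and sigma. Rods with zero contacts receive zero junctions.
#'
#' @param config a [scene_config()].
#' @param contacts contact table from [assign_contacts()].
#' @param rods rod table.
#' @param cones cone mosaic.
#' @return data.frame `id`, `rod_id`, `cone_id`, `length_nm`, `width_nm`,
#'   `distance_um`.
#' @export
sample_gap_junctions <- function(config, contacts, rods, cones) {
  validate_scene_config(config)
  if (nrow(contacts) == 0) stop("contacts must be non-empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "gapjunctions"))

  by_rod <- split(contacts$cone_id, contacts$rod_id)
  rod_ids <- names(by_rod)
  counts <- sample(1:6, length(rod_ids), replace = TRUE,
                   prob = config$gj_per_rod_pmf)
  cx <- stats::setNames(cones$x_um, cones$id)
  cy <- stats::setNames(cones$y_um, cones$id)
  rx <- stats::setNames(rods$x_um, rods$id)
  ry <- stats::setNames(rods$y_um, rods$id)

  rows <- vector("list", length(rod_ids))
  for (i in seq_along(rod_ids)) {
    rid <- rod_ids[i]
    cs <- by_rod[[i]]
    d <- sqrt((cx[cs] - rx[rid])^2 + (cy[cs] - ry[rid])^2)
    w <- 1 / pmax(d, 0.5)
    alloc <- if (length(cs) == 1) counts[i] else
      as.vector(stats::rmultinom(1, counts[i], prob = w / sum(w)))
    keep <- alloc > 0
    rows[[i]] <- data.frame(rod_id = rid, cone_id = rep(cs[keep], alloc[keep]),
                            stringsAsFactors = FALSE)
  }
  gj <- do.call(rbind, rows)
  m <- nrow(gj)
  mu <- truncnorm_latent_mean(config$gj_length_mean, config$gj_length_sd,
                              config$gj_length_min)
  gj$length_nm <- rtruncnorm_lower(m, mu, config$gj_length_sd,
                                   config$gj_length_min)
  gj$width_nm <- config$gj_width
  gj$distance_um <- stats::rlnorm(m, meanlog = log(config$distance_log_median),
                                  sdlog = config$distance_log_sigma)
  gj <- gj[order(gj$rod_id, gj$cone_id), , drop = FALSE]
  gj <- cbind(id = sprintf("gj%05d", seq_len(m)), gj)
  rownames(gj) <- NULL
  gj
}

#' Simulate a full synthetic OPL scene with ground truth
#'
#' Runs the generator stages in order (cones, rods, contacts, gap junctions,
#' planted puncta) from independent per-stage RNG substreams, so the whole
#' scene is reproducible from `config$seed` and any stage can be regenerated
#' alone.
#'
#' Planted puncta are the 3D positions of the sampled gap junctions: each sits
#' at its rod's opening center displaced by exactly the sampled distance, in a
#' direction biased toward the assigned cone and slightly downward, so
#' measured junction-to-opening distances recover the planted ones.
#'
#' @param config a [scene_config()].
#' @return Object of class `opl_scene`: `config`, `cones`, `rods`, `contacts`,
#'   `gap_junctions`, `planted_puncta`.
#' @export
simulate_scene <- function(config = scene_config()) {
  cones <- make_cone_mosaic(config)
  rods <- make_rod_field(config, cones)
  contacts <- assign_contacts(cones, rods, config$roof_tolerance)
  gj <- sample_gap_junctions(config, contacts, rods, cones)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(config$seed, "puncta"))
  rx <- stats::setNames(rods$x_um, rods$id)
  ry <- stats::setNames(rods$y_um, rods$id)
  rz <- stats::setNames(rods$z_um, rods$id)
  cx <- stats::setNames(cones$x_um, cones$id)
  cy <- stats::setNames(cones$y_um, cones$id)
  m <- nrow(gj)
  # direction: toward the assigned cone in xy (jittered), dipping downward
  base_ang <- atan2(cy[gj$cone_id] - ry[gj$rod_id],
                    cx[gj$cone_id] - rx[gj$rod_id])
  ang <- base_ang + stats::runif(m, -0.7, 0.7)
  dip <- stats::runif(m, 0, 0.6)          # fraction of the offset pointing down
  horiz <- sqrt(1 - dip^2)
  px <- rx[gj$rod_id] + gj$distance_um * horiz * cos(ang)
  py <- ry[gj$rod_id] + gj$distance_um * horiz * sin(ang)
  pz <- rz[gj$rod_id] - gj$distance_um * dip
  puncta <- data.frame(gj_id = gj$id, rod_id = gj$rod_id,
                       cone_id = gj$cone_id,
                       x_um = as.numeric(px), y_um = as.numeric(py),
                       z_um = as.numeric(pz), stringsAsFactors = FALSE)

  scene <- structure(
    list(config = config, cones = cones, rods = rods, contacts = contacts,
         gap_junctions = gj, planted_puncta = puncta),
    class = "opl_scene"
  )
  validate_scene(scene)
  scene
}

validate_scene <- function(scene) {
  stopifnot(!anyDuplicated(scene$cones$id), !anyDuplicated(scene$rods$id),
            !anyDuplicated(scene$gap_junctions$id))
  ek <- paste(scene$contacts$rod_id, scene$contacts$cone_id)
  stopifnot(!anyDuplicated(ek))
  gk <- paste(scene$gap_junctions$rod_id, scene$gap_junctions$cone_id)
  if (!all(gk %in% ek))
    stop("gap junction on a (rod, cone) pair absent from the contact list")
  invisible(scene)
}

#' @export
print.opl_scene <- function(x, ...) {
  cat("Synthetic OPL scene:", nrow(x$cones), "cones,", nrow(x$rods), "rods,",
      nrow(x$contacts), "contacts,", nrow(x$gap_junctions),
      "gap junctions (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a scene to plain-text files
#'
#' Writes `cones.csv` (with the field polygon as WKT), `rods.csv`,
#' `contacts.csv`, `gapjunctions.csv`, and `truth.json` (full configuration
#' plus derived generator parameters) into `dir`.
#'
#' @param scene an `opl_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  polys <- cone_polygons(scene$cones)
  cones_out <- scene$cones
  cones_out$field_wkt_polygon <-
    vapply(cones_out$id, function(id) polygon_to_wkt(polys[[id]]), character(1))
  utils::write.csv(cones_out, file.path(dir, "cones.csv"), row.names = FALSE)
  utils::write.csv(scene$rods, file.path(dir, "rods.csv"), row.names = FALSE)
  utils::write.csv(scene$contacts, file.path(dir, "contacts.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$gap_junctions, file.path(dir, "gapjunctions.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$planted_puncta, file.path(dir, "planted_puncta.csv"),
                   row.names = FALSE)
  truth <- unclass(scene$config)
  truth$variant_fractions <- as.list(truth$variant_fractions)
  truth$derived <- list(
    n_cones = nrow(scene$cones), n_rods = nrow(scene$rods),
    n_contacts = nrow(scene$contacts), n_gj = nrow(scene$gap_junctions),
    gj_length_latent_mean = truncnorm_latent_mean(
      scene$config$gj_length_mean, scene$config$gj_length_sd,
      scene$config$gj_length_min)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#' @param dir directory holding the CSV/JSON files.
#' @return An `opl_scene` (config restored from `truth.json`).
#' @export
read_scene <- function(dir) {
  cones <- utils::read.csv(file.path(dir, "cones.csv"),
                           stringsAsFactors = FALSE)
  polys <- lapply(cones$field_wkt_polygon, wkt_to_polygon)
  names(polys) <- cones$id
  cones$field_wkt_polygon <- NULL
  attr(cones, "polygons") <- polys
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  attr(cones, "region") <- c(width = truth$region_width,
                             height = truth$region_height)
  class(cones) <- c("cone_mosaic", "data.frame")
  cfg_fields <- setdiff(names(truth), "derived")
  cfg <- truth[cfg_fields]
  cfg$gj_per_rod_pmf <- as.numeric(cfg$gj_per_rod_pmf)
  cfg$variant_fractions <- unlist(cfg$variant_fractions)
  cfg <- do.call(scene_config, cfg)
  structure(
    list(config = cfg, cones = cones,
         rods = utils::read.csv(file.path(dir, "rods.csv"),
                                stringsAsFactors = FALSE),
         contacts = utils::read.csv(file.path(dir, "contacts.csv"),
                                    stringsAsFactors = FALSE),
         gap_junctions = utils::read.csv(file.path(dir, "gapjunctions.csv"),
                                         stringsAsFactors = FALSE),
         planted_puncta = utils::read.csv(file.path(dir, "planted_puncta.csv"),
                                          stringsAsFactors = FALSE)),
    class = "opl_scene"
  )
}
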