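#' A segmented gap-junction voxel patch
#'
#' One junction's voxels from a volume-EM segmentation, with voxel size and
#' the rod it belongs to. Indices are 0-based in (z, y, x) order; physical
#' positions are voxel-center coordinates.
#'
#' @param voxels integer matrix, n x 3, (z, y, x) indices.
#' @param voxel_size numeric length-3, nm per axis in (z, y, x) order.
#' @param rod_id optional rod id.
#' @param opening_center optional length-3 synaptic-opening center, um (z,y,x).
#' @param opening_radius optional opening radius, um.
#' @param check_connected verify the voxels form a single 26-connected
#'   component (default TRUE).
#' @return Object of class `junction_patch`.
#' @export
junction_patch <- function(voxels, voxel_size, rod_id = NA_character_,
                           opening_center = NULL, opening_radius = NA_real_,
                           check_connected = TRUE) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0) stop("patch must contain at least one voxel")
  stopifnot(ncol(voxels) == 3, length(voxel_size) == 3, all(voxel_size > 0))
  if (anyDuplicated(voxels)) voxels <- unique(voxels)
  if (check_connected && nrow(voxels) > 1) {
    comp <- connected_voxel_components(voxels)
    if (max(comp) > 1)
      stop("patch voxels are not a single 26-connected component")
  }
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 rod_id = rod_id, opening_center = opening_center,
                 opening_radius = opening_radius),
            class = "junction_patch")
}

# label 26-connected components among a set of integer voxel indices
connected_voxel_components <- function(voxels) {
  key <- paste(voxels[, 1], voxels[, 2], voxels[, 3])
  idx <- stats::setNames(seq_len(nrow(voxels)), key)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(voxels, 2, offs[k, ], "+")
    nk <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- nk %in% key
    if (any(hit))
      edges <- rbind(edges, cbind(which(hit), idx[nk[hit]]))
  }
  g <- igraph::graph_from_edgelist(
    matrix(as.character(if (is.null(edges)) integer(0) else edges), ncol = 2),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(nrow(voxels))),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  comp[as.character(seq_len(nrow(voxels)))]
}

#' Measure a junction patch as a simplified rectangle
#'
#' Rod/cone gap junctions are belt-like; their size is summarized as a
#' rectangle. A best plane is fitted to the voxel centers by total least
#' squares (SVD), the voxels are projected onto it, length is the extent along
#' the first in-plane principal axis (plus one voxel pitch along that
#' direction), and width is the projected patch area divided by length — the
#' mean width of the belt, not its maximum transverse extent. Length >= width
#' is enforced by swapping. Patches of fewer than 3 voxels are degenerate and
#' get the voxel diagonal for both dimensions.
#'
#' @param patch a [junction_patch()].
#' @return list: `length_nm`, `width_nm`, `degenerate` flag, `centroid_um`
#'   ((z,y,x) voxel-center centroid), `normal` (unit plane normal).
#' @export
measure_patch <- function(patch) {
  stopifnot(inherits(patch, "junction_patch"))
  vs <- patch$voxel_size
  centers <- sweep(patch$voxels + 0.5, 2, vs, "*")  # nm, (z,y,x)
  centroid_um <- colMeans(centers) / 1000
  if (nrow(centers) < 3) {
    d <- sqrt(sum(vs^2))
    return(list(length_nm = d, width_nm = d, degenerate = TRUE,
                centroid_um = centroid_um, normal = c(1, 0, 0)))
  }
  X <- sweep(centers, 2, colMeans(centers))
  sv <- svd(X)
  v1 <- sv$v[, 1]; v2 <- sv$v[, 2]; w <- sv$v[, 3]
  t1 <- X %*% v1
  pitch1 <- sum(abs(v1) * vs)
  len <- diff(range(t1)) + pitch1
  # silhouette of one voxel cuboid on the fitted plane
  vox_area <- abs(w[1]) * vs[2] * vs[3] + abs(w[2]) * vs[1] * vs[3] +
    abs(w[3]) * vs[1] * vs[2]
  area <- nrow(centers) * vox_area
  wid <- area / len
  if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
  list(length_nm = len, width_nm = wid, degenerate = FALSE,
       centroid_um = centroid_um, normal = w)
}

#' Distance from a junction patch to the synaptic-opening center
#'
#' Euclidean 3D distance (um) from the patch's voxel-center centroid to the
#' rod's synaptic-opening center.
#'
#' @param patch a [junction_patch()].
#' @param opening_center length-3 position in um, (z, y, x) order; defaults to
#'   the patch's own annotation.
#' @return distance in um.
#' @export
junction_distance <- function(patch, opening_center = patch$opening_center) {
  if (is.null(opening_center) || any(!is.finite(opening_center)))
    stop("opening_center must be a finite length-3 position")
  m <- measure_patch(patch)
  sqrt(sum((m$centroid_um - opening_center)^2))
}

#' Summarize junction-to-opening distances
#'
#' @param records data.frame with `id` and `distance_um` (e.g. the
#'   `gapjunctions.csv` schema).
#' @return list: `mean`, `sd`, `median` (um), `frac_within_1um`,
#'   `frac_within_2um`, `outlier_ids` (junctions beyond 2 um), `n`.
#' @export
summarize_distances <- function(records) {
  stopifnot(nrow(records) >= 1, "distance_um" %in% names(records))
  d <- records$distance_um
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0,
       median = stats::median(d),
       frac_within_1um = mean(d <= 1), frac_within_2um = mean(d <= 2),
       outlier_ids = records$id[d > 2], n = length(d))
}

#' Per-rod junction counts and total lengths
#'
#' For each rod with at least one junction: junction count, total length (um),
#' and mean length (nm). Rods whose *single* junction exceeds the 90th
#' percentile of all junction lengths are flagged — the "single large
#' junction" motif. Rods listed in `all_rod_ids` but absent from the records
#' are counted separately as empty, not folded into the summaries.
#'
#' @param records data.frame with `rod_id` and `length_nm`.
#' @param all_rod_ids optional vector of every rod id in the sample.
#' @return list: `per_rod` data.frame (`rod_id`, `count`, `total_um`,
#'   `mean_nm`, `single_large`), `count_summary` and `total_length_summary`
#'   ([quantity()]), `n_junctions`, `n_rods`, `empty_rods`.
#' @export
per_rod_counts_and_totals <- function(records, all_rod_ids = NULL) {
  stopifnot(nrow(records) >= 1, all(c("rod_id", "length_nm") %in%
                                      names(records)))
  q90 <- stats::quantile(records$length_nm, 0.9, names = FALSE)
  sp <- split(records$length_nm, records$rod_id)
  per_rod <- data.frame(
    rod_id = names(sp),
    count = vapply(sp, length, integer(1)),
    total_um = vapply(sp, function(l) sum(l) / 1000, numeric(1)),
    mean_nm = vapply(sp, mean, numeric(1)),
    single_large = vapply(sp, function(l) length(l) == 1 && l[1] > q90,
                          logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  empty <- if (is.null(all_rod_ids)) character(0)
           else setdiff(all_rod_ids, per_rod$rod_id)
  nr <- nrow(per_rod)
  list(
    per_rod = per_rod,
    count_summary = quantity(mean(per_rod$count),
                             if (nr > 1) stats::sd(per_rod$count) else 0,
                             if (nr > 1) "SD" else "none", n = nr, units = ""),
    total_length_summary = quantity(mean(per_rod$total_um),
                                    if (nr > 1) stats::sd(per_rod$total_um)
                                    else 0,
                                    if (nr > 1) "SD" else "none", n = nr,
                                    units = "um"),
    n_junctions = nrow(records), n_rods = nr, empty_rods = empty
  )
}
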