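# Quantification of puncta in multi-channel confocal volumes.

#' Label connected components in a 3D binary mask
#'
#' 26-connectivity, built on the components of the voxel-adjacency graph.
#'
#' @param mask 3D logical (or 0/1) array.
#' @return integer array of the same shape: 0 background, 1..k component
#'   labels.
#' @export
label_components_3d <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  fg <- which(mask != 0)
  lab <- array(0L, dims)
  if (length(fg) == 0) return(lab)
  pos <- arrayInd(fg, dims)
  key <- (pos[, 1] - 1) + dims[1] * ((pos[, 2] - 1) + dims[2] * (pos[, 3] - 1))
  lut <- stats::setNames(seq_along(fg), key)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[1:(nrow(offs) / 2), , drop = FALSE]  # half: undirected edges
  ea <- integer(0); eb <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nk <- (nb[ok, 1] - 1) + dims[1] * ((nb[ok, 2] - 1) +
                                         dims[2] * (nb[ok, 3] - 1))
    hit <- match(as.character(nk), names(lut))
    found <- !is.na(hit)
    if (any(found)) {
      ea <- c(ea, which(ok)[found])
      eb <- c(eb, as.integer(lut[hit[found]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(ea)) g <- igraph::add_edges(g, rbind(ea, eb))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

#' Otsu threshold of an intensity array
#'
#' Maximizes between-class variance on a 256-bin histogram.
#'
#' @param x numeric array or vector.
#' @param nbins histogram bins.
#' @return threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / nbins * diff(rng)
}

#' Threshold for sparse puncta channels
#'
#' Plain Otsu fails on puncta volumes because the background class holds
#' >99% of the voxels, pulling the threshold down to the noise floor and
#' marking a third of the volume as "foreground". When the first Otsu pass
#' leaves more than `refine_if_above` of the voxels above threshold — far
#' more than any plausible labeled structure — a second pass is computed on
#' those voxels alone, landing between the residual background tail and the
#' punctum cores. Channels whose first pass already yields a sparse
#' foreground (e.g. a structural channel with bright somata) are left alone.
#'
#' @param x numeric array or vector.
#' @param nbins histogram bins per pass.
#' @param refine_if_above foreground fraction above which the second pass
#'   triggers (default 0.1).
#' @return threshold on the intensity scale of `x`.
#' @export
puncta_threshold <- function(x, nbins = 256, refine_if_above = 0.1) {
  t1 <- otsu_threshold(x, nbins)
  v <- as.numeric(x)
  v2 <- v[v >= t1]
  if (length(v2) <= refine_if_above * length(v)) return(t1)
  if (length(v2) < 10 || diff(range(v2)) == 0) return(t1)
  otsu_threshold(v2, nbins)
}

#' Default minimum object size from the instrument PSF
#'
#' The volume, in voxels, of a sphere whose diameter is the PSF FWHM
#' (170 nm for the emulated Airyscan system); smaller objects are treated as
#' noise.
#'
#' @param voxel_size_nm length-3 voxel size (z, y, x) in nm.
#' @param psf_fwhm_nm PSF full width at half maximum, nm.
#' @return integer voxel count (at least 1).
#' @export
default_min_voxels <- function(voxel_size_nm, psf_fwhm_nm = 170) {
  vol_nm3 <- 4 / 3 * pi * (psf_fwhm_nm / 2)^3
  max(1L, floor(vol_nm3 / prod(voxel_size_nm)))
}

#' Count colocalized 3D objects in two channels
#'
#' Thresholds both channels, intersects the binary masks, labels 26-connected
#' components of the intersection, and keeps objects of at least `min_voxels`
#' voxels — the colocalized-puncta counting used to number Cx36 clusters per
#' cone pedicle.
#'
#' @param volA,volB 3D arrays of identical shape (or `opl_volume` channels).
#' @param thrA,thrB thresholds; `NULL` uses [puncta_threshold()] (two-pass
#'   Otsu) per channel.
#' @param min_voxels minimum object size in voxels; `NULL` uses
#'   [default_min_voxels()] when `voxel_size_nm` is given, else 1.
#' @param voxel_size_nm length-3 voxel size (z, y, x), nm; enables physical
#'   centroids and volumes.
#' @param origin_um physical position of the volume corner, (z, y, x) um
#'   (use the `origin_um` of an `opl_volume` so centroids land in scene
#'   coordinates).
#' @return Object of class `puncta_set`: data.frame `objects` (`id`,
#'   `n_voxels`, `z_um`, `y_um`, `x_um`, `volume_um3`), `count`, `thresholds`,
#'   `min_voxels`, and the label array as attribute `labels`.
#' @export
colocalize_count <- function(volA, volB, thrA = NULL, thrB = NULL,
                             min_voxels = NULL,
                             voxel_size_nm = c(150, 40, 40),
                             origin_um = c(0, 0, 0)) {
  if (!identical(dim(volA), dim(volB)))
    stop("volume shape mismatch: ", paste(dim(volA), collapse = "x"), " vs ",
         paste(dim(volB), collapse = "x"))
  if (is.null(thrA)) thrA <- puncta_threshold(volA)
  if (is.null(thrB)) thrB <- puncta_threshold(volB)
  stopifnot(thrA >= 0, thrB >= 0)
  if (is.null(min_voxels)) min_voxels <- default_min_voxels(voxel_size_nm)
  # a zero threshold means "any signal", not "everything incl. background"
  maskA <- if (thrA > 0) volA >= thrA else volA > 0
  maskB <- if (thrB > 0) volB >= thrB else volB > 0
  mask <- maskA & maskB
  lab <- label_components_3d(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  vs_um <- voxel_size_nm / 1000
  objects <- data.frame(id = integer(0), n_voxels = integer(0),
                        z_um = numeric(0), y_um = numeric(0),
                        x_um = numeric(0), volume_um3 = numeric(0))
  if (length(keep)) {
    relab <- array(0L, dim(lab))
    objects <- do.call(rbind, lapply(seq_along(keep), function(i) {
      w <- which(lab == keep[i])
      relab[w] <<- i
      pos <- arrayInd(w, dim(lab))
      ctr <- origin_um + (colMeans(pos) - 0.5) * vs_um
      data.frame(id = i, n_voxels = length(w), z_um = ctr[1], y_um = ctr[2],
                 x_um = ctr[3], volume_um3 = length(w) * prod(vs_um))
    }))
    lab <- relab
  } else {
    lab <- array(0L, dim(lab))
  }
  structure(list(objects = objects, count = nrow(objects),
                 thresholds = c(A = thrA, B = thrB),
                 min_voxels = min_voxels, voxel_size_nm = voxel_size_nm,
                 labels = lab),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat("Puncta set:", x$count, "colocalized 3D objects (thresholds",
      signif(x$thresholds[1], 3), "/", signif(x$thresholds[2], 3),
      ", min", x$min_voxels, "voxels)\n")
  invisible(x)
}

#' Assign puncta to rods and count clusters per rod
#'
#' Each punctum is assigned to the rod whose synaptic-opening center is
#' nearest its centroid. Puncta whose nearest and second-nearest rods differ
#' by less than `ambiguity_radius` are flagged ambiguous and excluded,
#' mirroring the manual exclusion of spherules too close to attribute a
#' cluster confidently.
#'
#' @param puncta a `puncta_set` from [colocalize_count()], or a data.frame
#'   with `z_um`, `y_um`, `x_um`.
#' @param rods data.frame with `id` and opening centers `x_um`, `y_um`,
#'   `z_um` (the `rods.csv` schema). Positions must be in the same frame as
#'   the puncta centroids.
#' @param ambiguity_radius exclusion margin, um.
#' @return list: `per_rod` (data.frame `rod_id`, `count`, zeros included),
#'   `assignments` (per-punctum rod and distances), `ambiguous` (excluded
#'   punctum ids), `mean_count` over rods with >= 1 punctum.
#' @export
clusters_per_rod <- function(puncta, rods, ambiguity_radius = 0.3) {
  pts <- if (inherits(puncta, "puncta_set")) puncta$objects else puncta
  if (nrow(pts) == 0) {
    per_rod <- data.frame(rod_id = rods$id, count = 0L)
    return(list(per_rod = per_rod, assignments = NULL,
                ambiguous = integer(0), mean_count = NaN))
  }
  D <- outer(pts$x_um, rods$x_um, "-")^2 +
       outer(pts$y_um, rods$y_um, "-")^2 +
       outer(pts$z_um, rods$z_um, "-")^2
  D <- sqrt(D)
  nearest <- apply(D, 1, which.min)
  d1 <- D[cbind(seq_len(nrow(pts)), nearest)]
  d2 <- if (ncol(D) > 1)
    apply(D, 1, function(r) sort(r, partial = 2)[2]) else rep(Inf, nrow(pts))
  ambiguous <- which(d2 - d1 < ambiguity_radius)
  keep <- setdiff(seq_len(nrow(pts)), ambiguous)
  counts <- table(factor(rods$id[nearest[keep]], levels = rods$id))
  per_rod <- data.frame(rod_id = names(counts), count = as.integer(counts),
                        stringsAsFactors = FALSE)
  list(per_rod = per_rod,
       assignments = data.frame(punctum = seq_len(nrow(pts)),
                                rod_id = rods$id[nearest], d1 = d1, d2 = d2,
                                stringsAsFactors = FALSE),
       ambiguous = ambiguous,
       mean_count = mean(per_rod$count[per_rod$count > 0]))
}
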