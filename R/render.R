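# Rendering of synthetic three-channel confocal volumes.
#
# Volumes are lists of 3D arrays indexed [z, y, x] (1-based in R; exported
# files use the 0-based (z, y, x) convention). Physical position of voxel
# (i, j, k) is ((i - 1) + 0.5) * voxel size on each axis, in um.

#' Render a synthetic three-channel confocal volume
#'
#' Rasterizes a scene into the three channels of the emulated immunostain:
#' \describe{
#'   \item{cx36}{Gaussian puncta at the planted gap-junction positions;}
#'   \item{cone}{pedicle discs plus ridged telodendrial polylines running from
#'     each pedicle to its contacted rods;}
#'   \item{rod}{two-lobed spherule bodies (vGlut1-like) with voids at the
#'     synaptic opening and at the mitochondrial compartment.}
#' }
#' A separable Gaussian PSF blur and additive Gaussian noise are then applied;
#' intensities are clamped non-negative. Deterministic given the scene's seed.
#'
#' @param scene an `opl_scene` from [simulate_scene()].
#' @param config imaging configuration (defaults to `scene$config`).
#' @param blur apply the PSF blur (disable for voxel-exact tests).
#' @param z_extent_um axial extent of the rendered volume, um.
#' @param max_voxels guard on total voxels per channel (default `512^3`).
#' @return Object of class `opl_volume`: `channels` (named list of 3D arrays),
#'   `voxel_size_nm` (z, y, x), `origin_um`.
#' @export
render_confocal_volume <- function(scene, config = scene$config, blur = TRUE,
                                   z_extent_um = 4, max_voxels = 512^3) {
  vx <- config$voxel_xy / 1000   # um
  vz <- config$voxel_z / 1000
  nx <- ceiling(config$region_width / vx)
  ny <- ceiling(config$region_height / vx)
  nz <- ceiling(z_extent_um / vz)
  if (as.numeric(nx) * ny * nz > max_voxels)
    stop("volume guard exceeded: ", format(as.numeric(nx) * ny * nz, big.mark = ","),
         " voxels requested, limit ", format(max_voxels, big.mark = ","))
  dims <- c(nz, ny, nx)
  ch <- list(cx36 = array(0, dims), cone = array(0, dims),
             rod = array(0, dims))

  # z convention: physical z_um measured upward from the pedicle plane at 0;
  # the volume spans [-1, z_extent_um - 1] so pedicles sit near the bottom.
  z0 <- -1
  deposit <- function(arr, pos_zyx_um, sigma_um, amp = 1) {
    # add an anisotropic Gaussian blob; pos and sigma are (z, y, x) in um
    ctr <- (pos_zyx_um - c(z0, 0, 0)) / c(vz, vx, vx) + 0.5  # voxel coords
    half <- ceiling(3 * sigma_um / c(vz, vx, vx))
    lo <- pmax(1, floor(ctr - half)); hi <- pmin(dims, ceiling(ctr + half))
    if (any(lo > hi)) return(arr)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    gz <- exp(-((iz - ctr[1]) * vz)^2 / (2 * sigma_um[1]^2))
    gy <- exp(-((iy - ctr[2]) * vx)^2 / (2 * sigma_um[2]^2))
    gx <- exp(-((ix - ctr[3]) * vx)^2 / (2 * sigma_um[3]^2))
    blob <- amp * outer(gz, outer(gy, gx))
    arr[iz, iy, ix] <- arr[iz, iy, ix] + blob
    arr
  }

  # channel 1: Cx36 puncta
  for (i in seq_len(nrow(scene$planted_puncta))) {
    p <- scene$planted_puncta[i, ]
    ch$cx36 <- deposit(ch$cx36, c(p$z_um, p$y_um, p$x_um),
                       c(0.09, 0.06, 0.06))
  }

  # channel 2: pedicle discs + telodendria to contacted rods
  rod_pos <- scene$rods[match(scene$contacts$rod_id, scene$rods$id), ]
  cone_pos <- scene$cones[match(scene$contacts$cone_id, scene$cones$id), ]
  for (i in seq_len(nrow(scene$cones))) {
    cn <- scene$cones[i, ]
    # pedicle: a flat disc emulated by a ring of blobs
    for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
      ch$cone <- deposit(ch$cone,
                         c(0.3, cn$y_um + 0.6 * cn$pedicle_radius_um * sin(ang),
                           cn$x_um + 0.6 * cn$pedicle_radius_um * cos(ang)),
                         c(0.25, 0.5, 0.5), amp = 0.6)
    }
  }
  if (nrow(scene$contacts)) {
    for (i in seq_len(nrow(scene$contacts))) {
      a <- c(0.6, cone_pos$y_um[i], cone_pos$x_um[i])       # pedicle top
      b <- c(rod_pos$z_um[i] - 0.2, rod_pos$y_um[i], rod_pos$x_um[i])
      steps <- max(2, ceiling(sqrt(sum((b - a)^2)) / 0.15))
      for (s in seq(0, 1, length.out = steps)) {
        ch$cone <- deposit(ch$cone, a + s * (b - a), c(0.12, 0.08, 0.08),
                           amp = 0.35)
      }
    }
  }
  # telodendrial tips: the cone process ends at each gap-junction contact, so
  # the cone channel carries signal at every planted punctum
  for (i in seq_len(nrow(scene$planted_puncta))) {
    p <- scene$planted_puncta[i, ]
    ch$cone <- deposit(ch$cone, c(p$z_um, p$y_um, p$x_um),
                       c(0.14, 0.12, 0.12), amp = 2)
  }

  # channel 3: rod spherule bodies with synaptic/mitochondrial voids
  for (i in seq_len(nrow(scene$rods))) {
    r <- scene$rods[i, ]
    body <- c(r$z_um + 0.55, r$y_um, r$x_um)
    ch$rod <- deposit(ch$rod, body, c(0.45, 0.55, 0.55), amp = 1)
    ch$rod <- deposit(ch$rod, c(r$z_um, r$y_um, r$x_um),
                      c(0.18, 0.22, 0.22), amp = -0.75)   # synaptic opening
    ch$rod <- deposit(ch$rod, c(r$z_um + 0.85, r$y_um, r$x_um),
                      c(0.15, 0.18, 0.18), amp = -0.4)    # mitochondrion
    ch$rod[ch$rod < 0] <- 0
  }

  if (blur) {
    sig_vox <- c(config$psf_sigma_z / config$voxel_z,
                 config$psf_sigma_xy / config$voxel_xy,
                 config$psf_sigma_xy / config$voxel_xy)
    ch <- lapply(ch, gaussian_blur_3d, sigma = sig_vox)
  }
  if (config$noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(stage_seed(config$seed, "render"))
    ch <- lapply(ch, function(a) {
      a <- a + stats::rnorm(length(a), 0, config$noise_sd)
      a[a < 0] <- 0
      a
    })
  }
  structure(list(channels = ch,
                 voxel_size_nm = c(z = config$voxel_z, y = config$voxel_xy,
                                   x = config$voxel_xy),
                 origin_um = c(z = z0, y = 0, x = 0)),
            class = "opl_volume")
}

#' Separable 3D Gaussian blur
#'
#' Convolves a 3D array with an axis-separable Gaussian kernel (zero-padded
#' borders). Sigmas are in voxels, (z, y, x) order; a sigma of 0 skips that
#' axis.
#'
#' @param arr 3D array.
#' @param sigma length-3 sigmas in voxels.
#' @return blurred array, same dimensions.
#' @export
gaussian_blur_3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3, length(sigma) == 3)
  blur_first_axis <- function(a, s) {
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    n <- dim(a)[1]
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      out[which(ok), , ] <- out[which(ok), , , drop = FALSE] +
        k[j] * a[src[ok], , , drop = FALSE]
    }
    out
  }
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    p <- perms[[ax]]
    arr <- aperm(blur_first_axis(aperm(arr, p), sigma[ax]), p)
  }
  arr
}

#' Write a multi-channel volume as TIFF
#'
#' Pages are z-slices, channels concatenated in channel order; intensities are
#' scaled to `[0, 1]` for storage and the scale plus voxel size are written to
#' a JSON sidecar (`<path>.json`) so [read_volume_tiff()] can restore the
#' original values.
#'
#' @param vol an `opl_volume`.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  mx <- max(1e-12, max(vapply(vol$channels, max, numeric(1))))
  pages <- list()
  for (nm in names(vol$channels)) {
    a <- vol$channels[[nm]] / mx
    for (i in seq_len(dim(a)[1])) pages[[length(pages) + 1]] <- a[i, , ]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  meta <- list(channels = names(vol$channels),
               dims_zyx = dim(vol$channels[[1]]),
               voxel_size_nm = as.list(vol$voxel_size_nm),
               origin_um = as.list(vol$origin_um), intensity_scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @return An `opl_volume`.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- meta$dims_zyx
  nz <- dims[1]
  chans <- list()
  for (ci in seq_along(meta$channels)) {
    a <- array(0, dims)
    for (i in seq_len(nz)) a[i, , ] <- pages[[(ci - 1) * nz + i]]
    chans[[meta$channels[ci]]] <- a * meta$intensity_scale
  }
  structure(list(channels = chans,
                 voxel_size_nm = unlist(meta$voxel_size_nm),
                 origin_um = unlist(meta$origin_um)),
            class = "opl_volume")
}
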