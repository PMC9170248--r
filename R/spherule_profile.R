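# Rod-spherule alignment/averaging and closed-contour perimeter profiling.
# 2D images are matrices indexed [row, col]; positions are (row, col) pixels;
# in the aligned frame the synaptic opening points toward +row ("6 o'clock").

bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
}

intensity_centroid <- function(img) {
  w <- sum(img)
  if (w == 0) return(c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2))
  r <- sum(row(img) * img) / w
  c <- sum(col(img) * img) / w
  c(r, c)
}

#' Align and average rod-spherule crops
#'
#' Each crop is translated so the spherule's intensity centroid sits at the
#' image center and rotated so its annotated synaptic opening points to
#' 6 o'clock (+row); the pixel-wise mean of the transformed crops is returned.
#' Multi-channel crops share the transform computed from the structural
#' channel.
#'
#' @param crops list of 2D matrices, or list of named lists of channel
#'   matrices (equal sizes).
#' @param opening_positions list (or n x 2 matrix) of (row, col) opening
#'   positions, one per crop; `NA` entries are an error.
#' @param structural channel used for the centroid when crops are
#'   multi-channel (default first channel).
#' @return A matrix, or named list of channel matrices, of the mean image.
#' @export
align_and_average <- function(crops, opening_positions, structural = NULL) {
  if (length(crops) < 2) stop("need at least 2 crops")
  multi <- !is.matrix(crops[[1]])
  if (!multi) crops <- lapply(crops, function(m) list(ch = m))
  if (is.null(structural)) structural <- names(crops[[1]])[1]
  if (is.matrix(opening_positions))
    opening_positions <- split(opening_positions, row(opening_positions)[, 1])
  bad <- which(vapply(opening_positions,
                      function(p) is.null(p) || any(is.na(p)), logical(1)))
  if (length(bad))
    stop("crop(s) without an annotated opening: index ",
         paste(bad, collapse = ", "))
  dims <- dim(crops[[1]][[structural]])
  center <- (dims + 1) / 2
  grid_r <- row(matrix(0, dims[1], dims[2])) - center[1]
  grid_c <- col(matrix(0, dims[1], dims[2])) - center[2]
  chans <- names(crops[[1]])
  acc <- stats::setNames(lapply(chans, function(.) matrix(0, dims[1], dims[2])),
                         chans)
  for (i in seq_along(crops)) {
    ctr <- intensity_centroid(crops[[i]][[structural]])
    op <- as.numeric(opening_positions[[i]])
    alpha <- atan2(op[1] - ctr[1], op[2] - ctr[2])  # angle of opening vector
    delta <- pi / 2 - alpha                          # rotate opening to +row
    cd <- cos(-delta); sd_ <- sin(-delta)
    src_r <- ctr[1] + grid_r * cd - grid_c * sd_
    src_c <- ctr[2] + grid_r * sd_ + grid_c * cd
    for (ch in chans) {
      v <- bilinear_sample(crops[[i]][[ch]], as.vector(src_r),
                           as.vector(src_c))
      acc[[ch]] <- acc[[ch]] + matrix(v, dims[1], dims[2])
    }
  }
  out <- lapply(acc, function(m) m / length(crops))
  if (!multi) out$ch else out
}

#' Linearize channel intensity around a closed perimeter
#'
#' Extracts the closed iso-contour of the structural channel, fits a periodic
#' cubic spline through arc-equidistant control points, and reports the mean
#' intensity of each channel within a band of width `band_width_nm` centered
#' on the curve, at `n_samples` equally spaced arc positions. The origin is
#' the 6 o'clock point (the curve point in the direction from the structure's
#' centroid to the synaptic opening; straight down for aligned spherules) and
#' the arc coordinate increases clockwise on the displayed image. Band
#' intensities are bilinear samples at 5 normal offsets across the band.
#'
#' @param channels named list of 2D matrices (equal sizes), including the
#'   structural channel.
#' @param structural name of the structural channel (vGlut1-like).
#' @param pixel_size_nm pixel size, nm.
#' @param band_width_nm band width centered on the curve, nm (default 272,
#'   i.e. 8 pixels at 34 nm).
#' @param n_samples number of arc positions.
#' @param iso_frac iso level as a fraction of the structural maximum.
#' @param opening optional (row, col) opening position; default: straight
#'   down from the centroid.
#' @param n_control spline control points.
#' @return data.frame of class `perimeter_profile`: `arc_um` plus one column
#'   per channel; attributes `length_um`, `band_width_nm`, `control_points`.
#' @export
perimeter_profile <- function(channels, structural = names(channels)[1],
                              pixel_size_nm, band_width_nm = 272,
                              n_samples = 100, iso_frac = 0.5,
                              opening = NULL, n_control = 60) {
  img <- channels[[structural]]
  stopifnot(is.matrix(img), pixel_size_nm > 0, band_width_nm > 0)
  level <- iso_frac * max(img)
  cl <- grDevices::contourLines(x = seq_len(nrow(img)), y = seq_len(ncol(img)),
                                z = img, levels = level)
  if (length(cl) == 0) stop("no iso-contour found at level ", signif(level, 3))
  lens <- vapply(cl, function(co)
    sum(sqrt(diff(co$x)^2 + diff(co$y)^2)), numeric(1))
  co <- cl[[which.max(lens)]]
  pts <- cbind(co$x, co$y)                      # (row, col)
  closed <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 2
  if (!closed) stop("extracted contour is open; cannot linearize perimeter")
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  if (!polygon_is_simple(pts)) stop("extracted contour is self-intersecting")

  # arc-equidistant control points, then a periodic cubic spline
  seglen <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s_ctrl <- seq(0, total, length.out = n_control + 1)[-(n_control + 1)]
  interp_at <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- pmin(i, nrow(pts))
    f <- (s - cum[i]) / pmax(seglen[i], 1e-12)
    nxt <- ifelse(i == nrow(pts), 1L, i + 1L)
    pts[i, , drop = FALSE] * (1 - f) + pts[nxt, , drop = FALSE] * f
  }
  ctrl <- interp_at(s_ctrl)
  tt <- c(s_ctrl, total)
  fine_n <- max(2000, 10 * n_samples)
  sx <- stats::spline(tt, c(ctrl[, 1], ctrl[1, 1]), method = "periodic",
                      n = fine_n)
  sy <- stats::spline(tt, c(ctrl[, 2], ctrl[1, 2]), method = "periodic",
                      n = fine_n)
  fine <- cbind(sx$y, sy$y)

  # orient clockwise as displayed (row axis pointing down)
  shoelace <- sum(fine[, 2] * c(fine[-1, 1], fine[1, 1]) -
                  c(fine[-1, 2], fine[1, 2]) * fine[, 1])
  if (shoelace < 0) fine <- fine[rev(seq_len(nrow(fine))), , drop = FALSE]

  seg <- sqrt(rowSums((fine - fine[c(2:nrow(fine), 1), ])^2))
  cumf <- c(0, cumsum(seg))
  L <- cumf[length(cumf)]

  ctr <- intensity_centroid(img)
  dir0 <- if (is.null(opening)) c(1, 0) else {
    v <- as.numeric(opening) - ctr
    v / sqrt(sum(v^2))
  }
  rel <- sweep(fine, 2, ctr)
  ang <- atan2(rel[, 1], rel[, 2])
  target <- atan2(dir0[1], dir0[2])
  dang <- abs(((ang - target + pi) %% (2 * pi)) - pi)
  o_idx <- which.min(dang)

  s_samp <- (seq_len(n_samples) - 1) / n_samples * L
  idx <- (o_idx - 1 + vapply(s_samp, function(s)
    findInterval(s, cumf, rightmost.closed = TRUE), integer(1)) - 1) %%
    nrow(fine) + 1
  pos <- fine[idx, , drop = FALSE]
  nxt <- fine[(idx %% nrow(fine)) + 1, , drop = FALSE]
  tang <- nxt - pos
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  nrm <- cbind(-tang[, 2], tang[, 1])

  half_px <- band_width_nm / pixel_size_nm / 2
  offsets <- c(-1, -0.5, 0, 0.5, 1) * half_px
  out <- data.frame(arc_um = s_samp * pixel_size_nm / 1000)
  for (ch in names(channels)) {
    vals <- matrix(0, n_samples, length(offsets))
    for (j in seq_along(offsets)) {
      vals[, j] <- bilinear_sample(channels[[ch]],
                                   pos[, 1] + offsets[j] * nrm[, 1],
                                   pos[, 2] + offsets[j] * nrm[, 2])
    }
    out[[ch]] <- rowMeans(vals)
  }
  structure(out, length_um = L * pixel_size_nm / 1000,
            band_width_nm = band_width_nm, control_points = ctrl,
            class = c("perimeter_profile", "data.frame"))
}
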