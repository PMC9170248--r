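test_that("rendering is deterministic and respects the voxel guard", {
  scene <- simulate_pedicle_scene(n_puncta = 5, seed = 2, region = 8,
                                  rod_spacing = 1.6, config = mini_config())
  v1 <- render_confocal_volume(scene)
  v2 <- render_confocal_volume(scene)
  expect_identical(v1$channels, v2$channels)
  expect_true(all(vapply(v1$channels, function(a) all(a >= 0), logical(1))))
  expect_error(render_confocal_volume(scene, max_voxels = 1000),
               "voxel")
})

test_that("noise-free empty scene renders an all-zero volume", {
  scene <- simulate_pedicle_scene(n_puncta = 1, seed = 1, region = 8,
                                  config = mini_config())
  scene$planted_puncta <- scene$planted_puncta[0, ]
  scene$contacts <- scene$contacts[0, ]
  scene$rods <- scene$rods[0, ]
  scene$cones <- scene$cones[0, , drop = FALSE]
  cfg <- scene$config
  cfg$noise_sd <- 0
  vol <- render_confocal_volume(scene, cfg, blur = FALSE)
  expect_true(all(vapply(vol$channels, function(a) all(a == 0), logical(1))))
})

test_that("separable blur preserves mass and spreads a point", {
  a <- array(0, c(9, 9, 9))
  a[5, 5, 5] <- 1
  b <- gaussian_blur_3d(a, c(1, 1, 1))
  expect_equal(sum(b), 1, tolerance = 1e-6)
  expect_lt(max(b), 1)
  expect_equal(which.max(b), which.max(a))
  # sigma 0 on an axis leaves that axis untouched
  c1 <- gaussian_blur_3d(a, c(0, 1, 1))
  expect_equal(sum(c1[5, , ]), 1, tolerance = 1e-6)
  expect_equal(sum(c1[4, , ]), 0)
})

test_that("volumes round-trip through TIFF with metadata", {
  scene <- simulate_pedicle_scene(n_puncta = 4, seed = 5, region = 8,
                                  rod_spacing = 1.6, config = mini_config())
  vol <- render_confocal_volume(scene)
  path <- file.path(withr::local_tempdir(), "vol.tif")
  write_volume_tiff(vol, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_volume_tiff(path)
  expect_equal(names(back$channels), names(vol$channels))
  expect_equal(back$voxel_size_nm, vol$voxel_size_nm)
  for (ch in names(vol$channels))
    expect_equal(back$channels[[ch]], vol$channels[[ch]], tolerance = 1e-5)
})

test_that("alignment recovers a rotated template and validates openings", {
  # template: off-center blob plus an opening marker down-right
  n <- 41
  mk <- function(theta) {
    img <- matrix(0, n, n)
    ctr <- c(21, 21)
    blob <- function(r0, c0, s, amp) {
      rr <- row(img) - r0; cc <- col(img) - c0
      amp * exp(-(rr^2 + cc^2) / (2 * s^2))
    }
    # body offset from center so rotation matters
    img <- img + blob(ctr[1] + 6 * sin(theta), ctr[2] + 6 * cos(theta), 5, 1)
    img
  }
  thetas <- c(pi / 2, pi / 4, pi, 5 * pi / 3)
  crops <- lapply(thetas, mk)
  openings <- lapply(thetas, function(t)
    c(21 + 14 * sin(t), 21 + 14 * cos(t)))
  avg <- align_and_average(crops, openings)
  # every aligned crop equals the theta = pi/2 (opening-down) template
  ref <- align_and_average(list(mk(pi / 2), mk(pi / 2)),
                           list(c(35, 21), c(35, 21)))
  expect_gt(stats::cor(as.vector(avg), as.vector(ref)), 0.98)
  # identical crops average to themselves
  same <- align_and_average(list(mk(pi / 2), mk(pi / 2), mk(pi / 2)),
                            rep(list(c(35, 21)), 3))
  expect_equal(same, ref, tolerance = 1e-8)
  expect_error(align_and_average(crops[1:2], list(c(1, 1), NULL)),
               "index 2")
  expect_error(align_and_average(crops[1], openings[1]), "at least 2")
})

test_that("perimeter profile is flat on a uniform ring and conserves mass", {
  n <- 101
  rr <- row(matrix(0, n, n)) - 51
  cc <- col(matrix(0, n, n)) - 51
  rad <- sqrt(rr^2 + cc^2)
  ring <- exp(-(rad - 30)^2 / (2 * 4^2))
  px <- 34
  prof <- perimeter_profile(list(vglut = ring), "vglut",
                            pixel_size_nm = px, band_width_nm = 8 * px,
                            n_samples = 90)
  expect_s3_class(prof, "perimeter_profile")
  # flat: coefficient of variation below 2%
  expect_lt(sd(prof$vglut) / mean(prof$vglut), 0.02)
  # arc positions strictly increasing, below curve length
  expect_true(all(diff(prof$arc_um) > 0))
  expect_lt(max(prof$arc_um), attr(prof, "length_um"))
  # the half-max iso-contour of the ring sits at r = 30 + sqrt(2 s^2 ln 2)
  rc <- 30 + sqrt(2 * 4^2 * log(2))
  expect_lt(abs(attr(prof, "length_um") - 2 * pi * rc * px / 1000) /
              (2 * pi * rc * px / 1000), 0.03)
  # band integral matches a mask integral (curvature corrections cancel on
  # a circle; residual error is the pixelized mask boundary)
  band <- prof$vglut * (attr(prof, "length_um") / nrow(prof)) *
    (8 * px / 1000)
  mask <- abs(rad - rc) <= 4
  mask_int <- sum(ring[mask]) * (px / 1000)^2
  expect_lt(abs(sum(band) - mask_int) / mask_int, 0.05)
})

test_that("planted puncta localize at +/-30 degrees around 6 o'clock", {
  n <- 101
  rr <- row(matrix(0, n, n)) - 51
  cc <- col(matrix(0, n, n)) - 51
  rad <- sqrt(rr^2 + cc^2)
  ring <- exp(-(rad - 30)^2 / (2 * 4^2))
  # puncta on the ring at +/-30 degrees from straight down
  ang <- c(pi / 2 - pi / 6, pi / 2 + pi / 6)   # atan2(drow, dcol)
  pr <- 51 + 30 * sin(ang)
  pc <- 51 + 30 * cos(ang)
  pun <- matrix(0, n, n)
  for (i in 1:2)
    pun <- pun + exp(-((row(pun) - pr[i])^2 + (col(pun) - pc[i])^2) /
                       (2 * 2.5^2))
  px <- 34
  ns <- 72
  prof <- perimeter_profile(list(vglut = ring, cx36 = pun), "vglut",
                            pixel_size_nm = px, band_width_nm = 8 * px,
                            n_samples = ns)
  L <- attr(prof, "length_um")
  # the two highest samples sit one arc-twelfth either side of the origin
  ord <- order(prof$cx36, decreasing = TRUE)
  peaks <- sort(prof$arc_um[ord[1:2]])
  step <- L / ns
  d1 <- min(abs(peaks[1] - L / 12), abs(peaks[1] - 11 * L / 12))
  d2 <- min(abs(peaks[2] - L / 12), abs(peaks[2] - 11 * L / 12))
  expect_lte(d1, step + 1e-9)
  expect_lte(d2, step + 1e-9)
  # the two peaks flank the origin on opposite sides
  expect_lt(peaks[1], L / 2)
  expect_gt(peaks[2], L / 2)
})

test_that("profile errors on open contours", {
  n <- 61
  stripe <- matrix(0, n, n)
  stripe[, 28:34] <- 1   # vertical band: iso-contour hits the image edge
  expect_error(perimeter_profile(list(v = stripe), "v", pixel_size_nm = 34),
               "open|no iso")
})

test_that("averaged synthetic spherule shows the Cx36 twin-peak motif", {
  # build aligned spherule crops straight from the generator's blob model:
  # body with a basal void (opening) and two flanking puncta
  n <- 81
  mkcrop <- function(jit_r, jit_c) {
    rr <- row(matrix(0, n, n)) - 41 - jit_r
    cc <- col(matrix(0, n, n)) - 41 - jit_c
    body <- exp(-(rr^2 + cc^2) / (2 * 14^2))
    void <- 0.8 * exp(-((rr - 16)^2 + cc^2) / (2 * 6^2))
    vglut <- pmax(body - void, 0)
    cxa <- exp(-((rr - 15)^2 + (cc - 8)^2) / (2 * 3^2))
    cxb <- exp(-((rr - 15)^2 + (cc + 8)^2) / (2 * 3^2))
    list(vglut = vglut, cx36 = cxa + cxb)
  }
  set.seed(91)
  crops <- lapply(1:6, function(i) mkcrop(runif(1, -2, 2), runif(1, -2, 2)))
  openings <- lapply(crops, function(cr) {
    ctr <- oplgj:::intensity_centroid(cr$vglut)
    ctr + c(16, 0)
  })
  avg <- align_and_average(crops, openings, structural = "vglut")
  prof <- perimeter_profile(avg, "vglut", pixel_size_nm = 34,
                            band_width_nm = 272, n_samples = 72,
                            iso_frac = 0.35)
  ns <- nrow(prof)
  third <- floor(ns / 3)
  basal <- c(1:third, (ns - third + 1):ns)      # around the 6 o'clock origin
  # structural channel dips at the opening relative to the rest of the curve
  expect_lt(min(prof$vglut[seq_len(6)]), mean(prof$vglut[-basal]))
  # Cx36 concentrates basally with two maxima flanking the origin
  expect_gt(mean(prof$cx36[basal]), 3 * mean(prof$cx36[-basal]))
  ord <- order(prof$cx36, decreasing = TRUE)
  L <- attr(prof, "length_um")
  peaks <- sort(prof$arc_um[ord[1:2]])
  expect_lt(peaks[1], L / 2)
  expect_gt(peaks[2], L / 2)
})
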