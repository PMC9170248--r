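test_that("scene generation is deterministic given config + seed", {
  cfg <- mini_config(seed = 5)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$cones, s2$cones)
  expect_identical(s1$rods, s2$rods)
  expect_identical(s1$contacts, s2$contacts)
  expect_identical(s1$gap_junctions, s2$gap_junctions)
  expect_identical(s1$planted_puncta, s2$planted_puncta)
  s3 <- simulate_scene(mini_config(seed = 6))
  expect_false(identical(s1$cones, s3$cones))
})

test_that("cone mosaic matches density, area target, and blue fraction", {
  cfg <- scene_config(region_width = 50, region_height = 50,
                      cone_density = 29 / 2500, seed = 3)
  realized <- vapply(1:8, function(seed) {
    nrow(make_cone_mosaic(scene_config(region_width = 50, region_height = 50,
                                       cone_density = 29 / 2500, seed = seed)))
  }, numeric(1))
  expect_true(all(abs(realized - 29) <= 6))
  # realized polygon areas track the 104 um^2 target within 5%
  big <- make_cone_mosaic(scene_config(region_width = 120, region_height = 120,
                                       cone_density = 0.015, seed = 2))
  expect_gte(nrow(big), 100)
  polys <- cone_polygons(big)
  areas <- vapply(polys, oplgj:::polygon_area, numeric(1))
  expect_lt(abs(mean(areas) - 104) / 104, 0.05)
  expect_equal(unname(areas), big$area_um2, tolerance = 1e-9)
  # error names the limiting parameter when no cone fits
  expect_error(make_cone_mosaic(scene_config(region_width = 2,
                                             region_height = 2,
                                             cone_density = 0.015)),
               "cone_density")
})

test_that("rod field count, variants, and placement behave", {
  cfg <- mini_config(seed = 4)
  cones <- make_cone_mosaic(cfg)
  rods <- make_rod_field(cfg, cones)
  expect_equal(nrow(rods), round(30 * nrow(cones)))
  # all-zero variant fractions give all-standard rods
  cfg0 <- mini_config(seed = 4,
                      variant_fractions = c(roof = 0, inverted = 0,
                                            low_row = 0))
  rods0 <- make_rod_field(cfg0, make_cone_mosaic(cfg0))
  expect_true(all(rods0$variant == "standard"))
  # default fractions populate every variant class in a ~29-cone scene
  cfg29 <- scene_config(seed = 8)
  rods29 <- make_rod_field(cfg29, make_cone_mosaic(cfg29))
  expect_setequal(unique(rods29$variant),
                  c("standard", "roof", "inverted", "low_row"))
})

test_that("contact assignment is geometric and closed under re-run", {
  cfg <- mini_config(seed = 9)
  scene <- simulate_scene(cfg)
  # re-running assignment on the exported tables reproduces contacts exactly
  again <- assign_contacts(scene$cones, scene$rods, cfg$roof_tolerance)
  expect_equal(scene$contacts, again)
  # degree-1 and degree-2 hand cases
  sq1 <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  sq2 <- cbind(c(2, 6, 6, 2), c(0, 0, 4, 4))
  cones <- data.frame(id = c("a", "b"), x_um = c(2, 4), y_um = c(2, 2),
                      is_blue = FALSE, area_um2 = 16, pedicle_radius_um = 1)
  attr(cones, "polygons") <- list(a = sq1, b = sq2)
  class(cones) <- c("cone_mosaic", "data.frame")
  rods <- data.frame(id = c("only_a", "both"), x_um = c(1, 3), y_um = c(2, 2),
                     z_um = 2, opening_radius_um = 0.14, variant = "standard")
  e <- assign_contacts(cones, rods)
  expect_equal(sum(e$rod_id == "only_a"), 1)
  expect_equal(sum(e$rod_id == "both"), 2)
  # invalid polygon is rejected with the cone id
  bowtie <- cbind(c(0, 2, 0, 2), c(0, 2, 2, 0))
  attr(cones, "polygons")$a <- bowtie
  expect_error(assign_contacts(cones, rods), "cone a")
})

test_that("gap-junction sampling honors pmf, lengths, and distances", {
  cfg <- mini_config(seed = 11)
  scene <- simulate_scene(cfg)
  # conservation: junction edges all exist in contacts
  ek <- paste(scene$contacts$rod_id, scene$contacts$cone_id)
  gk <- paste(scene$gap_junctions$rod_id, scene$gap_junctions$cone_id)
  expect_true(all(gk %in% ek))
  # point-mass pmf: exactly 3 junctions per contacted rod
  cfg3 <- mini_config(seed = 11,
                      gj_per_rod_pmf = c(0, 0, 1, 0, 0, 0))
  s3 <- simulate_scene(cfg3)
  counts <- table(s3$gap_junctions$rod_id)
  expect_true(all(counts == 3))
  expect_equal(nrow(s3$gap_junctions),
               3 * length(unique(s3$contacts$rod_id)))
})

test_that("length and distance distributions match their parameters", {
  # big sample via a dense small scene
  cfg <- scene_config(region_width = 60, region_height = 60,
                      cone_density = 0.015, seed = 13)
  scene <- simulate_scene(cfg)
  gj <- scene$gap_junctions
  expect_gte(length(unique(gj$rod_id)), 1000)
  # sample mean length within 3 SEM of 477 nm (latent mean calibrated)
  sem <- sd(gj$length_nm) / sqrt(nrow(gj))
  expect_lt(abs(mean(gj$length_nm) - 477), 3 * sem)
  expect_true(all(gj$length_nm >= 100))
  # distances: median near 0.435, 84% within 1 um
  expect_lt(abs(median(gj$distance_um) - 0.435), 0.02)
  expect_lt(abs(mean(gj$distance_um <= 1) - 0.84), 0.03)
  # moments track configured parameters within 3 standard errors
  sig <- cfg$distance_log_sigma
  mu <- log(cfg$distance_log_median)
  exp_mean <- exp(mu + sig^2 / 2)
  exp_sd <- exp_mean * sqrt(exp(sig^2) - 1)
  expect_lt(abs(mean(gj$distance_um) - exp_mean),
            3 * exp_sd / sqrt(nrow(gj)))
})

test_that("count pmf calibration hits requested moments", {
  p <- discretized_count_pmf(3.21, 1.23)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  m <- sum(p * (1:6))
  s <- sqrt(sum(p * (1:6)^2) - m^2)
  expect_equal(m, 3.21, tolerance = 1e-4)
  expect_equal(s, 1.23, tolerance = 1e-4)
  p2 <- discretized_count_pmf(2.48, 1.01)
  expect_equal(sum(p2 * (1:6)), 2.48, tolerance = 1e-4)
})

test_that("scene round-trips through CSV/JSON exactly enough to re-derive", {
  scene <- simulate_scene(mini_config(seed = 21))
  dir <- withr::local_tempdir()
  write_scene(scene, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cones.csv", "rods.csv", "contacts.csv", "gapjunctions.csv",
      "truth.json")))))
  back <- read_scene(dir)
  expect_equal(back$contacts, scene$contacts)
  expect_equal(back$gap_junctions$length_nm, scene$gap_junctions$length_nm,
               tolerance = 1e-9)
  # geometric closure from the re-read polygons
  again <- assign_contacts(back$cones, back$rods,
                           back$config$roof_tolerance)
  expect_equal(again, back$contacts)
})

test_that("scene config validation catches bad inputs", {
  expect_error(scene_config(blue_fraction = 1.5), "blue_fraction")
  expect_error(scene_config(gj_length_min = 600), "gj_length_min")
  expect_error(scene_config(gj_per_rod_pmf = rep(0.2, 6)), "summing to 1")
  expect_error(scene_config(cone_density = -1), "cone_density")
  expect_error(scene_config(noise_sd = -0.1), "noise_sd")
})
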