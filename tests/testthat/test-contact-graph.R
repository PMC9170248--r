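test_that("hand-wired graph metrics match worked examples", {
  g <- tiny_graph()
  conv <- convergence(g, c("c1", "c2"))
  expect_equal(unname(conv$counts), c(3, 3))
  # cone with no edges reports 0
  expect_equal(unname(convergence(g, "c3")$counts[["c3"]]), 1)
  g0 <- contact_graph(data.frame(rod_id = "r1", cone_id = "c1"),
                      cone_ids = c("c1", "c2"), rod_ids = "r1")
  expect_equal(unname(convergence(g0, "c2")$counts[["c2"]]), 0)
  div <- divergence(g)
  expect_equal(sort(unname(div$counts)), c(1, 1, 2, 3))
  expect_equal(div$summary$value, 7 / 4)
  expect_error(convergence(g, character(0)), "non-empty")
})

test_that("divergence means and histograms follow the edge list", {
  # {(r1,c1),(r2,c1),(r2,c2),(r3,c2)} -> mean 4/3 over contacted rods
  e <- data.frame(rod_id = c("r1", "r2", "r2", "r3"),
                  cone_id = c("c1", "c1", "c2", "c2"))
  g <- contact_graph(e, cone_ids = c("c1", "c2"),
                     rod_ids = c("r1", "r2", "r3"))
  expect_equal(divergence(g)$summary$value, 4 / 3)
  # all rods degree 1: histogram mass entirely at 1
  e1 <- data.frame(rod_id = c("r1", "r2"), cone_id = c("c1", "c2"))
  g1 <- contact_graph(e1, cone_ids = c("c1", "c2"), rod_ids = c("r1", "r2"))
  d1 <- divergence(g1)
  expect_equal(d1$summary$value, 1)
  expect_equal(unname(d1$histogram[["1"]]), 1)
  expect_equal(sum(d1$histogram), 1)
})

test_that("coverage follows summed areas over the region", {
  g1 <- contact_graph(data.frame(rod_id = "r1", cone_id = "c1"),
                      cone_ids = "c1", rod_ids = "r1",
                      cone_field_area = c(c1 = 40), region_area = 40)
  expect_equal(coverage(g1), 1)
  g2 <- contact_graph(data.frame(rod_id = "r1", cone_id = "c1"),
                      cone_ids = c("c1", "c2"), rod_ids = "r1",
                      cone_field_area = c(c1 = 20, c2 = 20), region_area = 40)
  expect_equal(coverage(g2), 1)
  gm <- contact_graph(data.frame(rod_id = "r1", cone_id = "c1"),
                      cone_ids = c("c1", "c2"), rod_ids = "r1",
                      cone_field_area = c(c1 = 20, c2 = NA), region_area = 40)
  expect_error(coverage(gm), "c2")
  # by-construction scene: 29 fields of exactly 104 in a region sized for 1.56
  cfg <- scene_config(field_area_sd = 1e-9, seed = 17)
  scene <- simulate_scene(cfg)
  g <- scene_contact_graph(scene)
  expected <- nrow(scene$cones) * 104 / (44 * 44)
  expect_equal(coverage(g), expected, tolerance = 1e-6)
})

test_that("shared/exclusive bookkeeping matches hand cases", {
  # {(r1,c1),(r1,c2),(r2,c1)}: shared(c1,c2)=1, exclusive c1=1, c2=0
  e <- data.frame(rod_id = c("r1", "r1", "r2"),
                  cone_id = c("c1", "c2", "c1"))
  g <- contact_graph(e, cone_ids = c("c1", "c2"), rod_ids = c("r1", "r2"))
  se <- shared_and_exclusive(g)
  expect_equal(se$shared["c1", "c2"], 1)
  expect_equal(se$shared["c2", "c1"], 1)
  expect_true(all(diag(se$shared) == 0))
  expect_equal(unname(se$exclusive), c(1, 0))
  # disjoint fields share nothing
  e2 <- data.frame(rod_id = c("r1", "r2"), cone_id = c("c1", "c2"))
  g2 <- contact_graph(e2, cone_ids = c("c1", "c2"), rod_ids = c("r1", "r2"))
  expect_true(all(shared_and_exclusive(g2)$shared == 0))
  # exclusivity judged against ALL cones, not just the central subset
  e3 <- data.frame(rod_id = c("r1", "r1"), cone_id = c("c1", "annulus"))
  g3 <- contact_graph(e3, cone_ids = c("c1", "annulus"), rod_ids = "r1",
                      central_cone_ids = "c1")
  expect_equal(unname(shared_and_exclusive(g3)$exclusive[["c1"]]), 0)
})

test_that("uncontacted bookkeeping reproduces the printed tally", {
  e <- data.frame(rod_id = sprintf("r%03d", 1:808),
                  cone_id = rep("c1", 808))
  g <- contact_graph(e, cone_ids = "c1", rod_ids = sprintf("r%03d", 1:811))
  u <- uncontacted_fraction(g)
  expect_equal(u$k, 3)
  expect_equal(u$n, 811)
  expect_equal(u$fraction, 3 / 811)
  expect_equal(u$percent, 0.4)   # 1 significant figure display
  # all contacted and none contacted
  expect_equal(uncontacted_fraction(g, sprintf("r%03d", 1:808))$k, 0)
  gempty <- contact_graph(e[0, ], cone_ids = "c1",
                          rod_ids = c("r1", "r2"))
  ue <- uncontacted_fraction(gempty)
  expect_equal(ue$fraction, 1)
})

test_that("graph metrics equal brute-force recomputation on small scenes", {
  for (seed in c(3, 14)) {
    cfg <- mini_config(seed = seed)
    scene <- simulate_scene(cfg)
    g <- scene_contact_graph(scene)
    expect_lte(length(g$cone_ids), 10)
    oracle <- brute_metrics(g$edges, g$cone_ids, g$rod_ids)
    conv <- convergence(g, g$cone_ids)
    expect_equal(unname(conv$counts), unname(oracle$convergence))
    div <- divergence(g)
    expect_equal(sort(unname(div$counts)),
                 sort(unname(oracle$divergence)))
    se <- shared_and_exclusive(g, g$cone_ids)
    expect_equal(se$shared[g$cone_ids, g$cone_ids],
                 oracle$shared[g$cone_ids, g$cone_ids])
    expect_equal(unname(se$exclusive), unname(oracle$exclusive))
    expect_equal(uncontacted_fraction(g)$k, oracle$uncontacted)
  }
})

test_that("edge-count conservation and monotonicity hold", {
  scene <- simulate_scene(mini_config(seed = 2))
  g <- scene_contact_graph(scene)
  conv <- convergence(g, g$cone_ids)
  div <- divergence(g)
  expect_equal(sum(conv$counts), nrow(g$edges))
  expect_equal(sum(div$counts), nrow(g$edges))
  # adding an edge never decreases any count
  have <- paste(g$edges$rod_id, g$edges$cone_id)
  cand <- expand.grid(rod_id = g$rod_ids, cone_id = g$cone_ids,
                      stringsAsFactors = FALSE)
  cand <- cand[!paste(cand$rod_id, cand$cone_id) %in% have, ][1, ]
  e2 <- rbind(g$edges, cand)
  g2 <- contact_graph(e2, g$cone_ids, g$rod_ids, g$cone_field_area,
                      g$region_area, g$central_cone_ids)
  expect_true(all(convergence(g2, g$cone_ids)$counts >= conv$counts))
  d2 <- divergence(g2)
  common <- intersect(names(d2$counts), names(div$counts))
  expect_true(all(d2$counts[common] >= div$counts[common]))
  # duplicate pads collapse to one edge
  g3 <- contact_graph(rbind(g$edges, g$edges[1, ]), g$cone_ids, g$rod_ids)
  expect_equal(nrow(g3$edges), nrow(g$edges))
})

test_that("reference-tuned scenes land in the simulated envelopes", {
  stats <- t(vapply(1:10, function(seed) {
    scene <- simulate_scene(scene_config(seed = seed))
    g <- scene_contact_graph(scene)
    r <- connectivity_report(g)
    h <- r$divergence_central_rods$histogram
    c(conv = r$convergence$summary$value,
      div = r$divergence_central_rods$summary$value,
      cov = r$coverage,
      m23 = h[["2"]] + h[["3"]],
      excl = r$exclusive_summary$value,
      unc = r$uncontacted$fraction)
  }, numeric(6)))
  means <- colMeans(stats)
  expect_gte(means[["conv"]], 37); expect_lte(means[["conv"]], 49)
  expect_gte(means[["div"]], 1.5); expect_lte(means[["div"]], 2.3)
  expect_gte(means[["cov"]], 1.4); expect_lte(means[["cov"]], 1.7)
  # convex fields cap the two/three-cone mass below the published 74%
  expect_gte(means[["m23"]], 0.5)
  expect_gte(means[["excl"]], 10); expect_lte(means[["excl"]], 20)
  expect_lte(means[["unc"]], 0.02)
})

test_that("graph constructor validates ids and areas", {
  e <- data.frame(rod_id = "rX", cone_id = "c1")
  expect_error(contact_graph(e, cone_ids = "c1", rod_ids = "r1"), "rX")
  e2 <- data.frame(rod_id = "r1", cone_id = "cX")
  expect_error(contact_graph(e2, cone_ids = "c1", rod_ids = "r1"), "cX")
  e3 <- data.frame(rod_id = "r1", cone_id = "c1")
  expect_error(contact_graph(e3, "c1", "r1", cone_field_area = c(c1 = -1)),
               "positive")
  expect_error(contact_graph(e3, "c1", "r1", central_cone_ids = "c9"),
               "subset")
})
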