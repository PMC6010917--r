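test_that("grids over a square pasture have the expected cell counts and areas", {
  p <- square_pasture(side = 800)
  g1 <- build_grid(p, "grid_1ha")
  expect_equal(nrow(g1), 64)
  expect_true(all(abs(g1$area_m2 - 1e4) < 0.01))
  gq <- build_grid(p, "quarter_16ha")
  expect_equal(nrow(gq), 4)
  expect_true(all(abs(gq$area_m2 - 16e4) < 0.01))
  # non-square pasture: edge cells are clipped, never larger than 1 ha
  o <- ref_origin()
  tri <- pasture("T1", "sheep",
                 rbind(c(o$easting_m, o$northing_m),
                       c(o$easting_m + 250, o$northing_m),
                       c(o$easting_m, o$northing_m + 250)))
  gt <- build_grid(tri, "grid_1ha")
  expect_true(all(gt$area_m2 <= 1e4 + 1e-6))
  expect_equal(sum(gt$area_m2), polygon_area_m2(tri$boundary), tolerance = 1e-9)
  expect_lt(nrow(gt), 9)
})

test_that("occupancy proportions count fixes into half-open cells and sum to 1", {
  p <- square_pasture(side = 800)
  g <- build_grid(p, "quarter_16ha")
  f <- fixes_from_xy(c(rep(100, 4), rep(600, 3), rep(100, 2), 700),
                     c(rep(100, 4), rep(100, 3), rep(600, 2), 700))
  pr <- occupancy_proportions(f, g)
  expect_equal(sum(pr$prop), 1, tolerance = 1e-12)
  expect_equal(sort(pr$prop), c(0.1, 0.2, 0.3, 0.4))
  # a fix exactly on an interior cell edge belongs to exactly one cell
  edge <- fixes_from_xy(400, 400)
  pre <- occupancy_proportions(edge, g)
  expect_equal(sum(pre$n), 1)
  expect_equal(pre$prop[pre$cell_id == "r1c1"], 1)
  # the pasture corner folds into the last cell
  corner <- fixes_from_xy(800, 800)
  expect_equal(sum(occupancy_proportions(corner, g)$n), 1)
  expect_error(occupancy_proportions(f[0, ], g), "zero fixes")
  # all fixes in one cell
  one <- occupancy_proportions(fixes_from_xy(rep(10, 5), rep(10, 5)), g)
  expect_equal(max(one$prop), 1)
})

test_that("occupancy differences are absolute, bounded and detect identity", {
  p <- square_pasture(side = 800)
  g <- build_grid(p, "quarter_16ha")
  f <- fixes_from_xy(c(rep(100, 4), rep(600, 6)), c(rep(100, 4), rep(600, 6)))
  ref <- occupancy_proportions(f, g)
  expect_equal(occupancy_difference(ref, ref)$max_abs_diff, 0)
  sub <- fixes_from_xy(c(rep(100, 3), rep(600, 2)), c(rep(100, 3), rep(600, 2)))
  d <- occupancy_difference(ref, occupancy_proportions(sub, g))
  expect_equal(d$max_abs_diff, 0.2, tolerance = 1e-12)
  expect_lte(d$mean_abs_diff, d$max_abs_diff)
  expect_true(all(d$per_cell$abs_diff >= 0 & d$per_cell$abs_diff <= 1))
  # proportions are invariant to duplicating every fix
  dup <- occupancy_proportions(f[rep(seq_len(nrow(f)), 2), ], g)
  expect_equal(dup$prop, ref$prop)
  g2 <- build_grid(p, "grid_1ha")
  expect_error(occupancy_difference(ref, occupancy_proportions(f, g2)),
               "different grids")
})

test_that("a quarter's difference is bounded by its nested 1-ha differences", {
  # nesting bound (triangle inequality): the signed differences of the 1-ha
  # cells inside a 16-ha quarter sum to the quarter's difference, so the
  # quarter's absolute difference cannot exceed their absolute sum
  p <- square_pasture(side = 800)
  gq <- build_grid(p, "quarter_16ha")
  g1 <- build_grid(p, "grid_1ha")
  cfg <- quick_sim_config(duration_days = 0.5)
  sim <- simulate_deployments(cfg)
  f <- crop_and_assign(sim$fixes$L01, list(P1 = sim_pasture(cfg)), "P1")
  quarter_of <- function(g) paste0("r", as.integer(g$y0 - min(g$y0) >= 400),
                                   "c", as.integer(g$x0 - min(g$x0) >= 400))
  for (s in standard_schemes(FALSE)) {
    sub <- apply_scheme(f, s)
    pq <- occupancy_proportions(f, gq)
    pq2 <- occupancy_proportions(sub, gq)
    p1 <- occupancy_proportions(f, g1)
    p12 <- occupancy_proportions(sub, g1)
    signed_q <- pq$prop - pq2$prop
    fine_abs <- tapply(abs(p1$prop - p12$prop), quarter_of(g1), sum)
    signed_sum <- tapply(p1$prop - p12$prop, quarter_of(g1), sum)
    expect_equal(as.numeric(signed_sum[pq$cell_id]), signed_q, tolerance = 1e-9)
    expect_true(all(abs(signed_q) <= as.numeric(fine_abs[pq$cell_id]) + 1e-12))
  }
})
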