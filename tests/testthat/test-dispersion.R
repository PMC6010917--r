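two_logger_fixes <- function(x1, y1, x2, y2, dt = 20) {
  rbind(fixes_from_xy(x1, y1, dt = dt, logger_id = "L01"),
        fixes_from_xy(x2, y2, dt = dt, logger_id = "L02"))
}

test_that("first fix per minute keeps the earliest of each local minute", {
  f <- fixes_from_xy(1:9, rep(0, 9))  # 20-s cadence: 3 fixes per minute
  out <- first_fix_per_minute(f)
  expect_equal(nrow(out), 3)
  expect_equal(out$easting_m, f$easting_m[c(1, 4, 7)])
  hour <- fixes_from_xy(seq_len(180), rep(0, 180))
  expect_equal(nrow(first_fix_per_minute(hour)), 60)
  expect_equal(nrow(first_fix_per_minute(f[0, ])), 0)
})

test_that("per-minute dispersion follows the two/three-logger rules", {
  # two loggers pinned 50 m apart -> constant series of 50
  n <- 30
  f <- two_logger_fixes(rep(0, n), rep(0, n), rep(50, n), rep(0, n))
  s <- minute_dispersion(f)
  expect_equal(unique(round(s$mean_dist_m, 9)), 50)
  expect_true(all(s$n_loggers == 2))
  # three collinear loggers at 0, 100, 200 -> mean pairwise 133.33
  f3 <- rbind(fixes_from_xy(0, 0, logger_id = "L01"),
              fixes_from_xy(100, 0, logger_id = "L02"),
              fixes_from_xy(200, 0, logger_id = "L03"))
  s3 <- minute_dispersion(f3)
  expect_equal(s3$mean_dist_m, (100 + 100 + 200) / 3, tolerance = 1e-9)
  # a minute where one logger is missing still yields the pair distance
  drop <- f3[-2, ]
  expect_equal(minute_dispersion(drop)$mean_dist_m, 200)
  # one logger only -> no value for that minute
  expect_equal(nrow(minute_dispersion(f3[1, , drop = FALSE])), 0)
})

test_that("dispersion is invariant to logger relabelling and translation", {
  set.seed(31)
  n <- 60
  f <- two_logger_fixes(cumsum(rnorm(n)), cumsum(rnorm(n)),
                        cumsum(rnorm(n)) + 30, cumsum(rnorm(n)))
  s <- minute_dispersion(f)
  swapped <- f
  swapped$logger_id <- ifelse(f$logger_id == "L01", "L02", "L01")
  expect_equal(minute_dispersion(swapped)$mean_dist_m, s$mean_dist_m)
  shifted <- f
  shifted$easting_m <- f$easting_m + 1234
  shifted$northing_m <- f$northing_m - 987
  expect_equal(minute_dispersion(shifted)$mean_dist_m, s$mean_dist_m,
               tolerance = 1e-12)
})

test_that("dispersion summary returns mean, median and 75th percentile", {
  s <- data.frame(mean_dist_m = c(10, 20, 30, 40))
  out <- dispersion_summary(s)
  expect_equal(out$mean_m, 25)
  expect_equal(out$p50_m, 25)
  expect_equal(out$n_minutes, 4)
  const <- data.frame(mean_dist_m = rep(50, 10))
  outc <- dispersion_summary(const)
  expect_equal(c(outc$mean_m, outc$p50_m, outc$p75_m), c(50, 50, 50))
  expect_error(dispersion_summary(data.frame(mean_dist_m = numeric())), "empty")
})

test_that("stationary OU herd reproduces the sqrt(pi) cohesion law", {
  # two animals, zero centroid motion, uniform activity: pairwise distance is
  # Rayleigh with mean spread_sd_m * sqrt(pi)
  cfg <- herd_sim_config(n_animals = 2, duration_days = 1, fine_step_s = 5,
                         centroid_speed_mean_mps = 0, spread_sd_m = 20,
                         attraction_rate_per_s = 1e-3,
                         activity_schedule = rep(1, 24),
                         gps_sd_m = 0, fix_failure_prob = 0, outlier_prob = 0,
                         seed = 41)
  sim <- simulate_herd(cfg)
  d <- sqrt(rowSums((sim$animals[[1]] - sim$animals[[2]])^2))
  # batch-means MC standard error (batches of 1 h >> OU relaxation time)
  bsize <- 3600 / cfg$fine_step_s
  nb <- floor(length(d) / bsize)
  bm <- colMeans(matrix(d[seq_len(nb * bsize)], nrow = bsize))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(d) - 20 * sqrt(pi)), 3 * se + 1e-9)
  # the dispersion module sees the same law through observed fixes
  f <- rbind(observe_fixes(sim, 1), observe_fixes(sim, 2))
  series <- minute_dispersion(f)$mean_dist_m
  nbm <- floor(length(series) / 60)
  bm_min <- colMeans(matrix(series[seq_len(nbm * 60)], nrow = 60))
  se_min <- sd(bm_min) / sqrt(nbm)
  expect_lt(abs(mean(series) - 20 * sqrt(pi)), 3 * se_min + 1e-9)
})
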