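test_that("daily distance sums consecutive same-date segments", {
  # square path: four 100-m legs back to the start
  sq <- fixes_from_xy(c(0, 100, 100, 0, 0), c(0, 0, 100, 100, 0))
  dd <- daily_distance(sq)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$distance_m, 400, tolerance = 1e-3)
  # dropping the middle corner cuts the corner
  bent <- fixes_from_xy(c(0, 100, 100), c(0, 0, 100))
  cut <- fixes_from_xy(c(0, 100), c(0, 100))
  expect_equal(daily_distance(bent)$distance_m, 200, tolerance = 1e-3)
  expect_equal(daily_distance(cut)$distance_m, sqrt(2) * 100, tolerance = 1e-3)
  # single fix in a day: zero distance, flagged
  one <- daily_distance(sq[1, , drop = FALSE])
  expect_equal(one$distance_m, 0)
  expect_true(one$too_few)
  # the overnight gap never contributes: two dates, each summed separately
  two_days <- rbind(
    fixes_from_xy(c(0, 100), c(0, 0),
                  t0 = as.POSIXct("2017-07-07 21:00:00", tz = "UTC")),
    fixes_from_xy(c(500, 600), c(0, 0),
                  t0 = as.POSIXct("2017-07-08 04:00:00", tz = "UTC")))
  dd2 <- daily_distance(two_days)
  expect_equal(dd2$distance_m, c(100, 100), tolerance = 1e-3)
})

test_that("percent of constant is 100 for identical inputs and scales linearly", {
  f <- fixes_from_xy(cumsum(rep(10, 30)), rep(0, 30))
  const <- daily_distance(f)
  expect_equal(percent_of_constant(const, const)$percent, 100)
  half <- const
  half$distance_m <- half$distance_m / 2
  expect_equal(percent_of_constant(half, const)$percent, 50)
  zero <- const
  zero$distance_m <- 0
  expect_equal(nrow(percent_of_constant(const, zero)), 0)
  other <- const
  other$date_local <- other$date_local + 30
  expect_error(percent_of_constant(const, other), "no matching")
})

test_that("hourly profile reflects the diel schedule and degenerate inputs", {
  still <- fixes_from_xy(rep(0, 200), rep(0, 200))
  hp <- hourly_profile(still)
  expect_true(all(hp$mean_dist_m[!is.na(hp$mean_dist_m)] == 0))
  cfg <- quick_sim_config(duration_days = 1, gps_sd_m = 0)
  sim <- simulate_deployments(cfg)
  hp2 <- hourly_profile(sim$fixes$L01)
  night <- hp2$mean_dist_m[hp2$hour %in% c(22, 23, 0, 1, 2, 3)]
  day <- hp2$mean_dist_m[!hp2$hour %in% c(22, 23, 0, 1, 2, 3)]
  expect_lt(max(night), min(day))
})

test_that("the correction fit recovers exact proportional relationships", {
  x <- c(800, 1500, 2600, 3100, 4200)
  m2 <- fit_correction(x, 2 * x)
  expect_equal(m2$beta, 2, tolerance = 1e-6)
  expect_lt(m2$sigma, 1e-3)
  m1 <- fit_correction(x, x)
  expect_equal(m1$beta, 1, tolerance = 1e-6)
  expect_error(fit_correction(rep(0, 5), x), "degenerate")
  expect_error(fit_correction(x[1:2], x[1:2]), "at least 3")
})

test_that("the MLE slope and Wald CI match the closed-form through-origin fit", {
  set.seed(51)
  x <- runif(60, 1000, 6000)
  y <- 1.6 * x + rnorm(60, 0, 200)
  m <- fit_correction(x, y)
  lmfit <- lm(y ~ 0 + x)
  expect_equal(m$beta, unname(coef(lmfit)), tolerance = 1e-6)
  # ML sigma uses n, lm uses n - 1 in the slope SE; rescale to compare
  se_ml_expected <- unname(sqrt(diag(vcov(lmfit)))) * sqrt(59 / 60)
  expect_equal(m$se, se_ml_expected, tolerance = 1e-4)
  prof <- fit_correction(x, y, ci_method = "profile")
  expect_equal(prof$ci95, m$ci95, tolerance = 1e-3)
  mi <- fit_correction(x, y, intercept = TRUE)
  lmi <- lm(y ~ x)
  expect_equal(mi$beta, unname(coef(lmi)[2]), tolerance = 1e-5)
})

test_that("parameter recovery: the 95% CI covers the generating slope", {
  set.seed(52)
  hits <- vapply(1:40, function(i) {
    x <- runif(60, 1000, 6000)
    y <- 1.6 * x + rnorm(60, 0, 0.05 * mean(x))
    ci <- fit_correction(x, y)$ci95
    ci[1] <= 1.6 && 1.6 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("validation flags both good and deliberately wrong corrections", {
  set.seed(53)
  x <- runif(40, 1000, 6000)
  y <- 1.7 * x + rnorm(40, 0, 150)
  model <- fit_correction(x[1:30], y[1:30])
  v <- validate_correction(model, x[31:40], y[31:40])
  expect_true(v$contains_one)
  ident <- fit_correction(x[1:30], x[1:30])
  v1 <- validate_correction(ident, x[31:40], x[31:40])
  expect_equal(v1$slope, 1, tolerance = 1e-6)
  wrong <- model
  wrong$beta <- 3
  vw <- validate_correction(wrong, x[31:40], y[31:40])
  expect_false(vw$contains_one)
  expect_error(validate_correction(model, numeric(), numeric()), "empty holdout")
})

test_that("correction models persist to JSON and back", {
  set.seed(54)
  x <- runif(30, 1000, 6000)
  models <- list(regular_5 = fit_correction(x, 1.3 * x + rnorm(30, 0, 100),
                                            scheme = "regular_5"))
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_models(models, path)
  back <- read_correction_models(path)
  expect_equal(back[[1]]$beta, models$regular_5$beta)
  expect_equal(back[[1]]$ci95, models$regular_5$ci95)
  expect_equal(back[[1]]$scheme, "regular_5")
})
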