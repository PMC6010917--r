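test_that("timestamp localisation is plain offset arithmetic with date rollover", {
  utc <- as.POSIXct("2017-07-07 03:00:00", tz = "UTC")
  expect_equal(format(localize_timestamp(utc, -6), "%Y-%m-%d %H:%M"),
               "2017-07-06 21:00")
  expect_equal(localize_timestamp(utc, 0), utc)
  past_midnight <- as.POSIXct("2017-07-07 00:30:00", tz = "UTC")
  expect_equal(format(localize_timestamp(past_midnight, -6), "%Y-%m-%d %H:%M"),
               "2017-07-06 18:30")
})

test_that("deduplication removes exact duplicates only, preserving order", {
  f <- fixes_from_xy(c(0, 10, 20), c(0, 0, 0))
  doubled <- f[rep(1:3, each = 2), ]
  out <- dedupe_records(doubled)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_duplicates"), 3L)
  expect_equal(out$easting_m, f$easting_m)
  # same timestamp, different coordinates: both kept
  g <- f
  g$easting_m[2] <- g$easting_m[1]
  g$time_local[2] <- g$time_local[1]
  g$time_utc[2] <- g$time_utc[1]
  expect_equal(nrow(dedupe_records(g)), 3)
  expect_equal(attr(dedupe_records(f), "n_duplicates"), 0L)
})

test_that("cropping keeps in-pasture fixes and counts removals by reason", {
  home <- square_pasture("P1", "sheep")
  neighbor <- square_pasture("P2", "cattle", shift_e = 800)
  pastures <- list(P1 = home, P2 = neighbor)
  # 5 inside, 1 just over the shared fence, 1 far outlier
  f <- fixes_from_xy(c(100, 400, 700, 50, 799, 801, 10000),
                     c(100, 400, 700, 750, 400, 400, 400))
  out <- crop_and_assign(f, pastures, "P1")
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "removed"),
               c(wrong_pasture = 1L, out_of_bounds = 1L))
  # identity when everything is inside
  all_in <- crop_and_assign(f[1:5, ], pastures, "P1")
  expect_equal(nrow(all_in), 5)
  expect_error(crop_and_assign(f, pastures, "P9"), "unknown pasture")
  # fence buffer retains near-fence fixes
  buffered <- crop_and_assign(f, pastures, "P1", fence_buffer = 2)
  expect_equal(nrow(buffered), 6)
})

test_that("deployment validity threshold is 1,000 retained fixes", {
  f <- fixes_from_xy(rep(0, 1000), rep(0, 1000))
  dep999 <- validate_deployment(deployment("L01", fixes = f[1:999, ]))
  dep1000 <- validate_deployment(deployment("L01", fixes = f))
  expect_false(dep999$valid)
  expect_true(dep1000$valid)
})

test_that("daytime filter keeps the half-open 04:00-22:00 local window", {
  t0 <- as.POSIXct("2017-07-07 00:00:00", tz = "UTC")
  f <- fixes_from_xy(rep(0, 4), rep(0, 4), t0 = t0)
  f$time_local <- t0 + c(3 * 3600 + 59 * 60 + 59, 4 * 3600,
                         21 * 3600 + 59 * 60 + 59, 22 * 3600)
  kept <- daytime_filter(f)
  expect_equal(as.numeric(kept$time_local) %% 86400 / 3600, c(4, 21.99972),
               tolerance = 1e-4)
  # a uniform 24-h day at 20-s cadence retains exactly 75% of fixes
  day <- fixes_from_xy(rep(0, 4320), rep(0, 4320), t0 = t0, dt = 20)
  expect_equal(nrow(daytime_filter(day)) / nrow(day), 0.75)
})

test_that("the cleaning pipeline is idempotent and its counts telescope", {
  pastures <- list(P1 = square_pasture("P1"),
                   P2 = square_pasture("P2", "cattle", shift_e = 800))
  sim <- simulate_deployments(quick_sim_config(outlier_prob = 0.01,
                                               duration_days = 0.5))
  fx <- sim$fixes$L01
  dir <- withr::local_tempdir()
  path <- file.path(dir, "L01.txt")
  write_logger_file(fx[1:1200, ], path)
  # plant duplicates and a truncated row
  lines <- readLines(path)
  writeLines(c(lines, lines[5:14], substr(lines[1], 1, 17)), path)
  dep <- suppressWarnings(
    ingest_deployment(path, pastures, "P1", utc_offset_hours = -6))
  cnt <- dep$qc$counts
  expect_equal(cnt[["n_rows"]], 1211)
  expect_equal(cnt[["n_malformed"]], 1)
  expect_equal(cnt[["n_duplicates"]], 10)
  expect_equal(cnt[["n_malformed"]] + cnt[["n_duplicates"]] +
                 cnt[["n_wrong_pasture"]] + cnt[["n_out_of_bounds"]] +
                 cnt[["n_retained"]], cnt[["n_rows"]])
  # idempotence: re-cleaning the cleaned output removes nothing
  path2 <- file.path(dir, "L01b.txt")
  write_logger_file(dep$fixes, path2)
  dep2 <- ingest_deployment(path2, pastures, "P1")
  expect_equal(dep2$qc$counts[["n_retained"]], cnt[["n_retained"]])
  expect_equal(sum(dep2$qc$counts[c("n_malformed", "n_duplicates",
                                    "n_wrong_pasture", "n_out_of_bounds")]), 0)
})

test_that("pasture GeoJSON boundaries read back as polygons with area", {
  pastures <- read_pastures(system.file("extdata", "pastures_synthetic.geojson",
                                        package = "herdtrack"))
  expect_named(pastures, c("C1", "S1"))
  expect_equal(pastures$C1$species, "cattle")
  expect_equal(pastures$C1$area_ha, 64, tolerance = 1e-6)
  expect_equal(nrow(pastures$S1$boundary), 4)
})
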