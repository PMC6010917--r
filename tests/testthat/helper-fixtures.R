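# Shared fixture builders. Everything is generated in code at test time.

# reference anchor used throughout: western North Dakota, UTM zone 13N
ref_origin <- function() {
  latlon_to_utm(46.0, -102.64)
}

# build a fix data.frame from planar offsets (metres) around the anchor
fixes_from_xy <- function(x, y, t0 = as.POSIXct("2017-07-07 06:00:00", tz = "UTC"),
                          dt = 20, logger_id = "L01") {
  o <- ref_origin()
  e <- o$easting_m + x
  n <- o$northing_m + y
  ll <- utm_to_latlon(e, n)
  tl <- t0 + (seq_along(x) - 1) * dt
  data.frame(logger_id = logger_id,
             time_utc = tl + 6 * 3600, time_local = tl,
             lat_dd = ll$lat_dd, lon_dd = ll$lon_dd,
             easting_m = e, northing_m = n,
             fix_quality = 1L, satellites = 8L)
}

# square test pasture of side `side` anchored at the reference origin
square_pasture <- function(id = "P1", species = "sheep", side = 800,
                           shift_e = 0, shift_n = 0) {
  o <- ref_origin()
  e0 <- o$easting_m + shift_e
  n0 <- o$northing_m + shift_n
  pasture(id, species,
          rbind(c(e0, n0), c(e0 + side, n0), c(e0 + side, n0 + side),
                c(e0, n0 + side)))
}

# a fast, small simulation config for unit tests
quick_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_animals = 2L, duration_days = 0.25, fine_step_s = 5,
         fix_failure_prob = 0, outlier_prob = 0, seed = 7L),
    list(...))
  do.call(herd_sim_config, args)
}
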