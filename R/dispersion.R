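#' First fix per local calendar minute
#'
#' Reduces each logger to at most one fix per local minute (the earliest),
#' so that dispersion between loggers is not inflated by the different
#' phases at which 20-s cadences fall within a minute.
#'
#' @param fixes Time-ordered fix data.frame with `time_local`.
#' @return The per-minute subsequence of `fixes`.
#' @export
first_fix_per_minute <- function(fixes) {
  if (nrow(fixes) == 0L) return(fixes)
  minute <- floor(as.numeric(fixes$time_local) / 60)
  out <- fixes[!duplicated(minute), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-minute herd dispersion within one pasture
#'
#' For every local minute in which at least two loggers have a valid
#' position, returns the mean pairwise planar (UTM Euclidean) distance among
#' the collared animals: with three loggers the mean of the three pairwise
#' distances, with two their distance, with fewer no value at all. Minutes
#' are never interpolated across gaps.
#'
#' @param fixes Fix data.frame for one pasture with a `logger_id` column
#'   (already daytime-filtered and time-ordered). Each logger is first
#'   reduced by [first_fix_per_minute()].
#' @return A data.frame with columns `minute` (POSIXct local minute start),
#'   `n_loggers`, `mean_dist_m`.
#' @export
minute_dispersion <- function(fixes) {
  stopifnot("logger_id" %in% names(fixes))
  per <- lapply(split(fixes, fixes$logger_id), first_fix_per_minute)
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L) {
    return(data.frame(minute = as.POSIXct(character(), tz = "UTC"),
                      n_loggers = integer(), mean_dist_m = numeric()))
  }
  key <- floor(as.numeric(per$time_local) / 60)
  groups <- split(seq_len(nrow(per)), key)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) == 0L) {
    return(data.frame(minute = as.POSIXct(character(), tz = "UTC"),
                      n_loggers = integer(), mean_dist_m = numeric()))
  }
  minute <- as.POSIXct(as.numeric(names(groups)) * 60,
                       origin = "1970-01-01", tz = "UTC")
  n <- vapply(groups, length, integer(1))
  md <- vapply(groups, function(idx) {
    mean(stats::dist(cbind(per$easting_m[idx], per$northing_m[idx])))
  }, numeric(1))
  out <- data.frame(minute = minute, n_loggers = n, mean_dist_m = unname(md))
  out[order(out$minute), , drop = FALSE]
}

#' Summarise a dispersion series
#'
#' Cohesion quantiles of the per-minute mean inter-animal distance: the
#' median answers "within what distance were the animals half the time",
#' the 75th percentile the headline "three quarters of the daytime period".
#'
#' @param series Data.frame from [minute_dispersion()] (or any vector-bearing
#'   data.frame with a `mean_dist_m` column).
#' @return One-row data.frame with `n_minutes`, `mean_m`, `p50_m`, `p75_m`.
#' @export
dispersion_summary <- function(series) {
  x <- series$mean_dist_m
  if (is.null(x) || length(x) == 0L) stop("empty dispersion series")
  data.frame(n_minutes = length(x), mean_m = mean(x),
             p50_m = unname(stats::quantile(x, 0.5)),
             p75_m = unname(stats::quantile(x, 0.75)))
}
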