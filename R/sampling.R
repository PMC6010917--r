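#' Define a logging scheme
#'
#' Three duty-cycle patterns are supported: `constant` (every 20-s fix kept),
#' `regular` (the first fix of every `interval_min`-minute clock window), and
#' `burst` (all fixes from the first `interval_min` minutes of each hour,
#' then silence -- the pattern a hardware power timer produces).
#'
#' @param pattern `"constant"`, `"regular"` or `"burst"`.
#' @param interval_min Window width (regular) or burst duration (burst) in
#'   minutes; conventionally 5 or 10. Ignored for `constant`.
#' @param base_interval_s Nominal cadence of the underlying data, seconds.
#' @return A `logging_scheme` object.
#' @export
logging_scheme <- function(pattern = c("constant", "regular", "burst"),
                           interval_min = NA, base_interval_s = 20) {
  pattern <- match.arg(pattern)
  if (pattern != "constant") {
    stopifnot(is.finite(interval_min), interval_min > 0)
  }
  structure(list(pattern = pattern, interval_min = interval_min,
                 base_interval_s = base_interval_s),
            class = "logging_scheme")
}

#' @export
print.logging_scheme <- function(x, ...) {
  cat(scheme_label(x), "\n")
  invisible(x)
}

#' Label for a logging scheme
#' @param scheme A [logging_scheme()].
#' @return Character label such as `"regular_5"` or `"constant"`.
#' @export
scheme_label <- function(scheme) {
  if (scheme$pattern == "constant") "constant"
  else paste0(scheme$pattern, "_", scheme$interval_min)
}

#' The four reduced logging schemes (plus constant)
#'
#' @param include_constant Include the constant scheme first (default TRUE).
#' @return Named list of [logging_scheme()] objects: regular 5/10 and burst
#'   5/10 minutes.
#' @export
standard_schemes <- function(include_constant = TRUE) {
  s <- list(
    regular_5 = logging_scheme("regular", 5),
    regular_10 = logging_scheme("regular", 10),
    burst_5 = logging_scheme("burst", 5),
    burst_10 = logging_scheme("burst", 10)
  )
  if (include_constant) s <- c(list(constant = logging_scheme("constant")), s)
  s
}

#' Assign timestamps to clock-aligned windows
#'
#' Windows are aligned to the clock (a 5-min window starts at :00, :05, ...)
#' and half-open: a fix at exactly 08:05:00 belongs to the 08:05 window.
#'
#' @param time_local POSIXct local timestamps.
#' @param width_min Window width in minutes; must divide 60.
#' @param phase_min Optional offset of window boundaries, minutes (for
#'   sensitivity analysis; default 0 = clock-aligned).
#' @return POSIXct window start times (the window id).
#' @export
assign_window <- function(time_local, width_min, phase_min = 0) {
  if (60 %% width_min != 0) stop("window width must divide 60 minutes")
  w <- width_min * 60
  s <- as.numeric(time_local) - phase_min * 60
  as.POSIXct(floor(s / w) * w + phase_min * 60,
             origin = "1970-01-01", tz = "UTC")
}

#' Subsample fixes as a regular logging scheme
#'
#' Keeps exactly the earliest fix of each non-empty clock window, emulating
#' a logger programmed to record one position every `width_min` minutes.
#' Ties on timestamp are broken by input order.
#'
#' @param fixes Time-ordered fix data.frame with `time_local`.
#' @param width_min Window width, minutes (must divide 60).
#' @param phase_min Window phase offset, minutes.
#' @return The subsampled fixes, a subsequence of the input.
#' @export
subsample_regular <- function(fixes, width_min, phase_min = 0) {
  if (nrow(fixes) == 0L) return(fixes)
  w <- assign_window(fixes$time_local, width_min, phase_min)
  out <- fixes[!duplicated(w), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample fixes as a burst logging scheme
#'
#' Keeps all fixes whose minute-of-hour falls in the first `duration_min`
#' minutes of each hour (configurable phase), emulating a power timer that
#' wakes the receiver once an hour.
#'
#' @param fixes Time-ordered fix data.frame with `time_local`.
#' @param duration_min Burst duration, minutes.
#' @param phase_min Minute-of-hour at which the burst starts (default 0).
#' @return The subsampled fixes, a subsequence of the input.
#' @export
subsample_burst <- function(fixes, duration_min, phase_min = 0) {
  if (nrow(fixes) == 0L) return(fixes)
  minute_of_hour <- (as.numeric(fixes$time_local) %% 3600) / 60
  keep <- minute_of_hour >= phase_min & minute_of_hour < phase_min + duration_min
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply a logging scheme to constant-logging fixes
#'
#' @param fixes Time-ordered fix data.frame.
#' @param scheme A [logging_scheme()].
#' @return The subsampled fixes (`constant` returns the input unchanged).
#' @export
apply_scheme <- function(fixes, scheme) {
  stopifnot(inherits(scheme, "logging_scheme"))
  switch(scheme$pattern,
         constant = fixes,
         regular = subsample_regular(fixes, scheme$interval_min),
         burst = subsample_burst(fixes, scheme$interval_min))
}

#' Project battery life under a duty-cycled logging scheme
#'
#' Multiplies a measured baseline battery life by a duty-cycle extension
#' factor, reporting hours, whole days, and days to one decimal.
#'
#' @param base_hours Baseline battery life in hours (e.g. the mean logging
#'   hours observed under constant logging).
#' @param extension_factor Battery-life multiplier of the duty cycle.
#' @return List with `hours`, `days` (whole days, floored) and
#'   `days_decimal` (one decimal).
#' @examples
#' battery_life_projection(171, 7.5)   # 1282.5 h
#' battery_life_projection(1306, 1)    # 54 whole days
#' @export
battery_life_projection <- function(base_hours, extension_factor) {
  stopifnot(base_hours > 0, extension_factor > 0)
  hours <- base_hours * extension_factor
  list(hours = hours, days = floor(hours / 24),
       days_decimal = round(hours / 24, 1))
}
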