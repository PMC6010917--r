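#' Ellipsoidal geodesic distance between coordinate pairs
#'
#' Thin wrapper around [geosphere::distGeo()] (WGS84 ellipsoid), the standard
#' tool for point-to-point distances in animal telemetry. At pasture scale
#' the WGS84/NAD83 difference is far below GPS error.
#'
#' @param lat1,lon1,lat2,lon2 Decimal-degree coordinates (vectorised).
#' @return Distances in metres.
#' @export
geodesic_distance_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Centroid of a unit's fixes
#'
#' Arithmetic mean of decimal-degree coordinates -- adequate at pasture
#' scale, where a degree is locally linear to well below GPS precision.
#'
#' @param fixes Fix data.frame with `lat_dd` and `lon_dd`.
#' @return Named numeric vector `c(lat_dd =, lon_dd =)`.
#' @export
fixes_centroid <- function(fixes) {
  if (nrow(fixes) == 0L) stop("cannot take the centroid of zero fixes")
  c(lat_dd = mean(fixes$lat_dd), lon_dd = mean(fixes$lon_dd))
}

#' 95% circular error probability of a set of fixes
#'
#' The CEP at level `prob` is the empirical `prob` quantile of geodesic
#' distances from each fix to a reference point. Against the unit's own
#' centroid it measures precision (how tightly positions cluster); against a
#' surveyed georeference it measures accuracy.
#'
#' @param fixes Fix data.frame with `lat_dd` and `lon_dd`.
#' @param reference Numeric `c(lat, lon)` reference point, decimal degrees.
#' @param prob Quantile level (default 0.95).
#' @param type Quantile interpolation rule passed to [stats::quantile()];
#'   default 7, linear interpolation between order statistics.
#' @return CEP radius in metres.
#' @export
cep95 <- function(fixes, reference, prob = 0.95, type = 7) {
  if (nrow(fixes) == 0L) stop("cannot compute CEP of zero fixes")
  if (nrow(fixes) < 20L)
    warning("fewer than 20 fixes; CEP quantile will be unstable")
  d <- geodesic_distance_m(fixes$lat_dd, fixes$lon_dd,
                           reference[[1]], reference[[2]])
  unname(stats::quantile(d, prob, type = type, names = FALSE))
}

#' Precision and accuracy CEP protocol across receiver units
#'
#' For each unit (stationary over a surveyed point, logging at 20-s
#' intervals), computes precision CEP95 (distances to the unit's own fix
#' centroid) and accuracy CEP95 (distances to the known georeference), then
#' summarises across units as mean +/- standard error
#' (SE = sample SD / sqrt(number of units)).
#'
#' @param fixes Fix data.frame with columns `unit_id`, `lat_dd`, `lon_dd`.
#' @param reference Numeric `c(lat, lon)` of the known georeference point.
#' @param prob Quantile level (default 0.95).
#' @return A data.frame with one row per unit (`unit_id`, `n_fixes`,
#'   `precision_cep95_m`, `accuracy_cep95_m`, `centroid_lat`,
#'   `centroid_lon`), with a `summary` attribute holding the across-unit
#'   mean and SE of each measure.
#' @export
run_qc_protocol <- function(fixes, reference, prob = 0.95) {
  stopifnot("unit_id" %in% names(fixes))
  units <- split(fixes, fixes$unit_id)
  small <- vapply(units, function(u) nrow(u) < 2L, logical(1))
  if (any(small)) {
    warning("excluding unit(s) with < 2 fixes: ",
            paste(names(units)[small], collapse = ", "))
    units <- units[!small]
  }
  if (length(units) == 0L) stop("no units with >= 2 fixes")
  rows <- lapply(names(units), function(id) {
    u <- units[[id]]
    ctr <- fixes_centroid(u)
    data.frame(unit_id = id, n_fixes = nrow(u),
               precision_cep95_m = cep95(u, ctr, prob),
               accuracy_cep95_m = cep95(u, reference, prob),
               centroid_lat = ctr[["lat_dd"]], centroid_lon = ctr[["lon_dd"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  attr(out, "summary") <- data.frame(
    measure = c("precision_cep95_m", "accuracy_cep95_m"),
    mean_m = c(mean(out$precision_cep95_m), mean(out$accuracy_cep95_m)),
    se_m = c(se(out$precision_cep95_m), se(out$accuracy_cep95_m))
  )
  out
}
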