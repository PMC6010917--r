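#' @title Transverse Mercator projection for UTM zone coordinates
#' @description
#' Forward and inverse UTM projection on the GRS80 ellipsoid (the reference
#' ellipsoid of NAD83, the datum used for all planar coordinates in this
#' package). The implementation is the exact-to-machine-precision Krüger
#' series in the third flattening, truncated at sixth order; truncation error
#' is far below a nanometre, so round-trips are limited only by floating
#' point.
#' @name utm
NULL

# GRS80 ellipsoid (NAD83)
.tm <- local({
  a <- 6378137
  f <- 1 / 298.257222101
  n <- f / (2 - f)
  A <- a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 - 127 * n^5 / 288 + 7891 * n^6 / 37800,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 - 1983433 * n^6 / 1935360,
    61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 + 167603 * n^6 / 181440,
    49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
    34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
    212378941 * n^6 / 319334400
  )
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 + 96199 * n^6 / 604800,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 - 1118711 * n^6 / 3870720,
    17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 + 5569 * n^6 / 90720,
    4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
    4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
    20648693 * n^6 / 638668800
  )
  # conformal -> geodetic latitude series
  delta <- c(
    2 * n - 2 * n^2 / 3 - 2 * n^3 + 116 * n^4 / 45 + 26 * n^5 / 45 - 2854 * n^6 / 675,
    7 * n^2 / 3 - 8 * n^3 / 5 - 227 * n^4 / 45 + 2704 * n^5 / 315 + 2323 * n^6 / 945,
    56 * n^3 / 15 - 136 * n^4 / 35 - 1262 * n^5 / 105 + 73814 * n^6 / 2835,
    4279 * n^4 / 630 - 332 * n^5 / 35 - 399572 * n^6 / 14175,
    4174 * n^5 / 315 - 144838 * n^6 / 6237,
    601676 * n^6 / 22275
  )
  list(a = a, f = f, e = sqrt(f * (2 - f)), A = A,
       alpha = alpha, beta = beta, delta = delta,
       k0 = 0.9996, false_easting = 5e5, false_northing = 0)
})

#' Central meridian of a UTM zone
#' @param zone UTM zone number (1-60).
#' @return Longitude of the zone's central meridian, decimal degrees.
#' @export
utm_central_meridian <- function(zone) {
  stopifnot(zone >= 1, zone <= 60)
  -183 + 6 * zone
}

#' Project geographic coordinates to UTM
#'
#' Forward transverse Mercator projection (GRS80/NAD83) to UTM easting and
#' northing in metres. The default zone is 13N, covering the western North
#' Dakota rangeland this package's workflow was designed around. Coordinates
#' well outside the nominal 6-degree zone are still projected, with a warning,
#' because field fixes occasionally stray.
#'
#' @param lat_dd,lon_dd Latitude and longitude in signed decimal degrees
#'   (north and east positive). Vectorised.
#' @param zone UTM zone number; default 13.
#' @return A data.frame with columns `easting_m` and `northing_m`.
#' @seealso [utm_to_latlon()] for the inverse.
#' @examples
#' latlon_to_utm(46.0, -102.64)
#' @export
latlon_to_utm <- function(lat_dd, lon_dd, zone = 13L) {
  stopifnot(length(lat_dd) == length(lon_dd))
  if (any(abs(lat_dd) > 84, na.rm = TRUE))
    stop("latitude outside the UTM validity band (|lat| <= 84)")
  lon0 <- utm_central_meridian(zone)
  dlon <- lon_dd - lon0
  if (any(abs(dlon) > 6, na.rm = TRUE))
    warning("coordinates more than 6 degrees from the zone ", zone,
            " central meridian; projection applied anyway")
  phi <- lat_dd * pi / 180
  lam <- dlon * pi / 180
  e <- .tm$e
  t_ <- sinh(atanh(sin(phi)) - e * atanh(e * sin(phi)))
  xi_p <- atan2(t_, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t_^2 + cos(lam)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:6) {
    xi <- xi + .tm$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + .tm$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  data.frame(easting_m = .tm$false_easting + .tm$k0 * .tm$A * eta,
             northing_m = .tm$false_northing + .tm$k0 * .tm$A * xi)
}

#' Inverse UTM projection
#'
#' Inverse transverse Mercator (GRS80/NAD83): UTM easting/northing back to
#' decimal degrees. Exact inverse of [latlon_to_utm()] to floating-point
#' precision.
#'
#' @param easting_m,northing_m UTM coordinates in metres (northern hemisphere
#'   convention, false northing 0). Vectorised.
#' @param zone UTM zone number; default 13.
#' @return A data.frame with columns `lat_dd` and `lon_dd`.
#' @export
utm_to_latlon <- function(easting_m, northing_m, zone = 13L) {
  stopifnot(length(easting_m) == length(northing_m))
  lon0 <- utm_central_meridian(zone)
  xi <- (northing_m - .tm$false_northing) / (.tm$k0 * .tm$A)
  eta <- (easting_m - .tm$false_easting) / (.tm$k0 * .tm$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - .tm$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - .tm$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(pmin(1, pmax(-1, sin(xi_p) / cosh(eta_p))))
  phi <- chi
  for (j in 1:6) phi <- phi + .tm$delta[j] * sin(2 * j * chi)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  data.frame(lat_dd = phi * 180 / pi, lon_dd = lon0 + lam * 180 / pi)
}
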