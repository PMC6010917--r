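#' Convert an NMEA degrees decimal-minutes field to decimal degrees
#'
#' GPS receivers report position in the NMEA `ddmm.mmmm` (latitude) or
#' `dddmm.mmmm` (longitude) layout: whole degrees concatenated with decimal
#' minutes, plus a hemisphere letter. `"4916.46","N"` means 49 degrees
#' 16.46 minutes north, i.e. 49.2743333 decimal degrees.
#'
#' @param field Character vector of NMEA coordinate fields, e.g. `"4916.46"`.
#'   The two digits immediately before the decimal point are the whole
#'   minutes; everything before them is whole degrees.
#' @param hemisphere Character vector of hemisphere letters, `"N"`, `"S"`,
#'   `"E"` or `"W"`; south and west are returned negative.
#' @return Numeric vector of signed decimal degrees.
#' @examples
#' nmea_to_decimal("4916.46", "N")  # 49.27433...
#' @export
nmea_to_decimal <- function(field, hemisphere) {
  stopifnot(length(field) == length(hemisphere))
  field <- trimws(field)
  hemisphere <- toupper(trimws(hemisphere))
  bad_hem <- !hemisphere %in% c("N", "S", "E", "W")
  if (any(bad_hem))
    stop("invalid hemisphere flag at position ", which(bad_hem)[1],
         ": '", hemisphere[which(bad_hem)[1]], "'")
  ok <- grepl("^[0-9]{3,5}(\\.[0-9]+)?$", field)
  if (any(!ok))
    stop("malformed NMEA coordinate field at position ", which(!ok)[1],
         ": '", field[which(!ok)[1]], "'")
  dot <- regexpr(".", field, fixed = TRUE)
  dot[dot < 0] <- nchar(field)[dot < 0] + 1L
  deg <- as.numeric(substr(field, 1L, dot - 3L))
  mins <- as.numeric(substr(field, dot - 2L, nchar(field)))
  if (any(mins >= 60))
    stop("minutes >= 60 in NMEA field at position ", which(mins >= 60)[1],
         ": '", field[which(mins >= 60)[1]], "'")
  dd <- deg + mins / 60
  ifelse(hemisphere %in% c("S", "W"), -dd, dd)
}

#' Encode decimal degrees as an NMEA degrees decimal-minutes field
#'
#' Inverse of [nmea_to_decimal()]. Latitude degrees are zero-padded to two
#' digits, longitude to three, matching the logger dialect.
#'
#' @param dd Signed decimal degrees (vectorised).
#' @param coord `"lat"` or `"lon"`; controls degree-field width and
#'   hemisphere letters.
#' @param digits Decimal-minute digits to keep (default 4; at 4 digits the
#'   encode/decode round trip is exact to well under 1e-6 degree).
#' @return A data.frame with character columns `field` and `hemisphere`.
#' @examples
#' decimal_to_nmea(49.2743333, "lat")  # 4916.4600, N
#' @export
decimal_to_nmea <- function(dd, coord = c("lat", "lon"), digits = 4L) {
  coord <- match.arg(coord)
  maxabs <- if (coord == "lat") 90 else 180
  if (any(!is.finite(dd)) || any(abs(dd) > maxabs))
    stop("decimal degrees out of range for ", coord)
  hem <- if (coord == "lat") ifelse(dd < 0, "S", "N") else ifelse(dd < 0, "W", "E")
  x <- abs(dd)
  deg <- floor(x)
  mins <- round((x - deg) * 60, digits)
  carry <- mins >= 60
  deg[carry] <- deg[carry] + 1
  mins[carry] <- 0
  degw <- if (coord == "lat") 2L else 3L
  field <- sprintf(paste0("%0", degw, "d%0", digits + 3L, ".", digits, "f"),
                   as.integer(deg), mins)
  data.frame(field = field, hemisphere = hem, stringsAsFactors = FALSE)
}

# Raw logger dialect: header-less ASCII CSV, one row per fix:
# ddmmyy,hhmmss.sss,fix_quality,lat ddmm.mmmm,N|S,lon dddmm.mmmm,E|W,satellites
.logger_row_ok <- function(parts) {
  length(parts) == 8L &&
    grepl("^[0-9]{6}$", parts[1]) &&
    grepl("^[0-9]{6}(\\.[0-9]+)?$", parts[2]) &&
    grepl("^[0-9]+$", parts[3]) &&
    grepl("^[0-9]{4}(\\.[0-9]+)?$", parts[4]) &&
    parts[5] %in% c("N", "S") &&
    grepl("^[0-9]{5}(\\.[0-9]+)?$", parts[6]) &&
    parts[7] %in% c("E", "W") &&
    grepl("^[0-9]+$", parts[8]) &&
    as.numeric(substr(parts[4], 3, nchar(parts[4]))) < 60 &&
    as.numeric(substr(parts[6], 4, nchar(parts[6]))) < 60
}

#' Read a raw GPS logger file
#'
#' Parses the header-less comma-separated files written by the collar
#' dataloggers (and by [write_logger_file()]):
#' `ddmmyy,hhmmss.sss,fix_quality,ddmm.mmmm,N|S,dddmm.mmmm,E|W,satellites`.
#' Malformed rows -- field loggers truncate lines at power loss -- are
#' skipped, counted, and reported in a warning, never fatal.
#'
#' @param path Path to one logger file.
#' @return A data.frame of raw records, one per well-formed row in file
#'   order, with columns `utc_date`, `utc_time`, `fix_quality`, `lat_field`,
#'   `lat_hemisphere`, `lon_field`, `lon_hemisphere`, `satellites`. The
#'   number of skipped rows is attached as attribute `n_malformed`.
#' @export
parse_logger_file <- function(path) {
  if (!file.exists(path)) stop("logger file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(utc_date = character(), utc_time = character(),
                      fix_quality = integer(), lat_field = character(),
                      lat_hemisphere = character(), lon_field = character(),
                      lon_hemisphere = character(), satellites = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    attr(empty, "n_malformed") <- 0L
    return(empty)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  parts <- lapply(parts, trimws)
  ok <- vapply(parts, .logger_row_ok, logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " malformed row(s) skipped in ", basename(path))
  if (!any(ok)) {
    warning("no well-formed rows in ", basename(path))
    attr(empty, "n_malformed") <- n_bad
    return(empty)
  }
  m <- do.call(rbind, parts[ok])
  out <- data.frame(
    utc_date = m[, 1], utc_time = m[, 2],
    fix_quality = as.integer(m[, 3]),
    lat_field = m[, 4], lat_hemisphere = m[, 5],
    lon_field = m[, 6], lon_hemisphere = m[, 7],
    satellites = as.integer(m[, 8]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write fixes as a raw logger file
#'
#' Re-encodes decimal-degree fixes in the raw logger dialect so that
#' simulator output is round-trippable through [parse_logger_file()]. An
#' empty fix set produces an empty file (the dialect has no header).
#'
#' @param fixes A fix data.frame with at least `time_utc` (POSIXct, UTC),
#'   `lat_dd` and `lon_dd`; optional `fix_quality` and `satellites` columns
#'   (defaults 1 and 8).
#' @param path Output file path.
#' @param digits Decimal-minute digits in the encoded coordinates.
#' @return `path`, invisibly.
#' @export
write_logger_file <- function(fixes, path, digits = 4L) {
  if (nrow(fixes) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write logger file: ", path)
    return(invisible(path))
  }
  lat <- decimal_to_nmea(fixes$lat_dd, "lat", digits)
  lon <- decimal_to_nmea(fixes$lon_dd, "lon", digits)
  fq <- if ("fix_quality" %in% names(fixes)) fixes$fix_quality else 1L
  sat <- if ("satellites" %in% names(fixes)) fixes$satellites else 8L
  rows <- sprintf("%s,%s.000,%d,%s,%s,%s,%s,%d",
                  format(fixes$time_utc, "%d%m%y", tz = "UTC"),
                  format(fixes$time_utc, "%H%M%S", tz = "UTC"),
                  as.integer(fq), lat$field, lat$hemisphere,
                  lon$field, lon$hemisphere, as.integer(sat))
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write logger file: ", path)
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}
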