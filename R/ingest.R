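#' Shift a UTC timestamp to local clock time
#'
#' Local time is modelled as a fixed integer-hour offset from UTC (the field
#' site's standard offset); the returned POSIXct carries the UTC timezone
#' label but reads as local clock time, so date rollover is plain arithmetic.
#'
#' @param time_utc POSIXct timestamps in UTC.
#' @param offset_hours Hours to add (default -6, US Mountain/Central
#'   boundary in summer).
#' @return POSIXct local clock times.
#' @examples
#' localize_timestamp(as.POSIXct("2017-07-07 03:00:00", tz = "UTC"), -6)
#' @export
localize_timestamp <- function(time_utc, offset_hours = -6) {
  stopifnot(is.finite(offset_hours))
  time_utc + offset_hours * 3600
}

#' Remove exact duplicate rows
#'
#' Rows identical in every field are reduced to their first occurrence
#' (duplicates arise when a previous deployment's data remain on the SD
#' card); original order is preserved. The number removed is attached as
#' attribute `n_duplicates`.
#'
#' @param records A data.frame (raw records or fixes).
#' @return The deduplicated data.frame.
#' @export
dedupe_records <- function(records) {
  keep <- !duplicated(records)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(!keep)
  out
}

#' Convert raw logger records to fixes
#'
#' Turns parsed NMEA records into analysis-ready fixes: UTC and local
#' timestamps, signed decimal degrees, and UTM easting/northing (zone 13N,
#' NAD83 by default).
#'
#' @param records Data.frame from [parse_logger_file()].
#' @param utc_offset_hours Local-time offset, hours (default -6).
#' @param zone UTM zone (default 13).
#' @return A fix data.frame with columns `time_utc`, `time_local`, `lat_dd`,
#'   `lon_dd`, `easting_m`, `northing_m`, `fix_quality`, `satellites`.
#' @export
records_to_fixes <- function(records, utc_offset_hours = -6, zone = 13L) {
  if (nrow(records) == 0L) {
    return(data.frame(time_utc = as.POSIXct(character(), tz = "UTC"),
                      time_local = as.POSIXct(character(), tz = "UTC"),
                      lat_dd = numeric(), lon_dd = numeric(),
                      easting_m = numeric(), northing_m = numeric(),
                      fix_quality = integer(), satellites = integer()))
  }
  t_utc <- as.POSIXct(strptime(paste(records$utc_date, records$utc_time),
                               format = "%d%m%y %H%M%OS", tz = "UTC"))
  if (anyNA(t_utc)) stop("unparseable timestamp in records")
  lat <- nmea_to_decimal(records$lat_field, records$lat_hemisphere)
  lon <- nmea_to_decimal(records$lon_field, records$lon_hemisphere)
  utm <- latlon_to_utm(lat, lon, zone)
  data.frame(time_utc = t_utc,
             time_local = localize_timestamp(t_utc, utc_offset_hours),
             lat_dd = lat, lon_dd = lon,
             easting_m = utm$easting_m, northing_m = utm$northing_m,
             fix_quality = records$fix_quality,
             satellites = records$satellites)
}

#' Construct a pasture
#'
#' @param id Pasture identifier.
#' @param species `"cattle"` or `"sheep"`.
#' @param boundary n x 2 matrix of UTM (easting, northing) vertices of a
#'   simple polygon, metres.
#' @return A `pasture` object (list with `id`, `species`, `boundary`,
#'   `area_ha`).
#' @export
pasture <- function(id, species = c("cattle", "sheep"), boundary) {
  species <- match.arg(species)
  boundary <- .close_ring(boundary)
  if (nrow(boundary) < 3) stop("pasture boundary needs at least 3 vertices")
  area <- polygon_area_m2(boundary)
  if (area <= 0) stop("pasture polygon has zero area")
  structure(list(id = as.character(id), species = species,
                 boundary = boundary, area_ha = area / 1e4),
            class = "pasture")
}

#' @export
print.pasture <- function(x, ...) {
  cat(sprintf("Pasture %s (%s): %.1f ha, %d boundary vertices\n",
              x$id, x$species, x$area_ha, nrow(x$boundary)))
  invisible(x)
}

#' Read pasture boundaries from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features whose coordinates are UTM
#' metres (easting, northing) and whose properties carry `id` and `species`.
#'
#' @param path GeoJSON file path.
#' @return Named list of [pasture()] objects.
#' @export
read_pastures <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    pasture(f$properties$id, f$properties$species, m)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Crop fixes to their assigned pasture
#'
#' Keeps only fixes inside the assigned pasture polygon. Discarded fixes are
#' counted by reason: `wrong_pasture` (inside some other pasture, e.g. the
#' wrong side of a shared fence) and `out_of_bounds` (inside none). Because
#' GPS error near fences is the usual cause of wrong-side fixes, an optional
#' fence buffer retains fixes within `fence_buffer` metres outside the
#' assigned boundary.
#'
#' @param fixes Fix data.frame with `easting_m`/`northing_m`.
#' @param pastures Named list of [pasture()] objects (non-overlapping).
#' @param assigned_pasture_id Id of the pasture the animal was stocked in.
#' @param fence_buffer Metres of tolerance outside the assigned fence
#'   (default 0: pure point-in-polygon).
#' @return The retained fixes, with attribute `removed`, a named integer
#'   vector `c(wrong_pasture =, out_of_bounds =)`.
#' @export
crop_and_assign <- function(fixes, pastures, assigned_pasture_id,
                            fence_buffer = 0) {
  if (!assigned_pasture_id %in% names(pastures))
    stop("unknown pasture id: ", assigned_pasture_id)
  target <- pastures[[assigned_pasture_id]]
  inside <- .in_polygon(fixes$easting_m, fixes$northing_m, target$boundary)
  if (fence_buffer > 0 && any(!inside)) {
    out_idx <- which(!inside)
    near <- .dist_to_outline(fixes$easting_m[out_idx], fixes$northing_m[out_idx],
                             target$boundary) <= fence_buffer
    inside[out_idx[near]] <- TRUE
  }
  rejected <- which(!inside)
  wrong <- logical(length(rejected))
  others <- pastures[setdiff(names(pastures), assigned_pasture_id)]
  for (p in others) {
    wrong <- wrong | .in_polygon(fixes$easting_m[rejected],
                                 fixes$northing_m[rejected], p$boundary)
  }
  out <- fixes[inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(wrong_pasture = sum(wrong),
                            out_of_bounds = sum(!wrong))
  out
}

#' Construct a deployment
#'
#' A deployment is all fixes from one logger on one animal in one pasture
#' trial, plus its validity status (set by [validate_deployment()]).
#'
#' @param logger_id,animal_id,pasture_id,trial_month Identifiers.
#' @param fixes Fix data.frame (will be time-ordered).
#' @return A `deployment` object.
#' @export
deployment <- function(logger_id, animal_id = logger_id, pasture_id = NA,
                       trial_month = NA, fixes) {
  fixes <- fixes[order(fixes$time_utc), , drop = FALSE]
  rownames(fixes) <- NULL
  structure(list(logger_id = logger_id, animal_id = animal_id,
                 pasture_id = pasture_id, trial_month = trial_month,
                 fixes = fixes, valid = NA, qc = list()),
            class = "deployment")
}

#' @export
print.deployment <- function(x, ...) {
  cat(sprintf("Deployment %s (animal %s, pasture %s): %d fixes, valid = %s\n",
              x$logger_id, x$animal_id, x$pasture_id, nrow(x$fixes), x$valid))
  invisible(x)
}

#' Validate a deployment by minimum fix count
#'
#' A deployment is analysable only if it retained at least `min_fixes`
#' cleaned positions (default 1,000); invalid deployments are excluded from
#' analyses but kept for QC reporting.
#'
#' @param dep A [deployment()].
#' @param min_fixes Minimum retained fixes (default 1000).
#' @return The deployment with `valid` set.
#' @export
validate_deployment <- function(dep, min_fixes = 1000L) {
  dep$valid <- nrow(dep$fixes) >= min_fixes
  dep$qc$min_fixes <- min_fixes
  dep
}

#' Keep only daytime fixes
#'
#' Livestock activity between 22:00 and 04:00 local is minimal, so analyses
#' use the daytime window only. The window is half-open on local clock time:
#' a fix at exactly `start_hour`:00:00 is kept, one at `end_hour`:00:00 is
#' not.
#'
#' @param fixes Fix data.frame with a `time_local` column.
#' @param start_hour,end_hour Window bounds in local hours (defaults 4
#'   and 22).
#' @return The daytime subset of `fixes`.
#' @export
daytime_filter <- function(fixes, start_hour = 4, end_hour = 22) {
  secs <- as.numeric(fixes$time_local) %% 86400
  hr <- secs / 3600
  out <- fixes[hr >= start_hour & hr < end_hour, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full cleaning pipeline on one logger file
#'
#' Parse, convert, deduplicate, crop to the assigned pasture, and validate.
#' Every removal is counted by reason and the counts sum exactly to
#' (rows in - fixes out).
#'
#' @param path Raw logger file.
#' @param pastures Named list of [pasture()] objects.
#' @param assigned_pasture_id The pasture this logger's animal was in.
#' @param logger_id,animal_id,trial_month Deployment identifiers.
#' @param utc_offset_hours,zone Passed to [records_to_fixes()].
#' @param min_fixes Validity threshold, see [validate_deployment()].
#' @param fence_buffer See [crop_and_assign()].
#' @return A validated [deployment()]; `$qc$counts` holds
#'   `n_rows`, `n_malformed`, `n_duplicates`, `n_wrong_pasture`,
#'   `n_out_of_bounds`, `n_retained`.
#' @export
ingest_deployment <- function(path, pastures, assigned_pasture_id,
                              logger_id = basename(path),
                              animal_id = logger_id, trial_month = NA,
                              utc_offset_hours = -6, zone = 13L,
                              min_fixes = 1000L, fence_buffer = 0) {
  rec <- parse_logger_file(path)
  n_malformed <- attr(rec, "n_malformed")
  n_rows <- nrow(rec) + n_malformed
  rec <- dedupe_records(rec)
  n_dup <- attr(rec, "n_duplicates")
  fixes <- records_to_fixes(rec, utc_offset_hours, zone)
  fixes <- crop_and_assign(fixes, pastures, assigned_pasture_id, fence_buffer)
  removed <- attr(fixes, "removed")
  dep <- deployment(logger_id, animal_id, assigned_pasture_id, trial_month,
                    fixes)
  dep <- validate_deployment(dep, min_fixes)
  dep$qc$counts <- c(n_rows = n_rows, n_malformed = n_malformed,
                     n_duplicates = n_dup,
                     n_wrong_pasture = unname(removed["wrong_pasture"]),
                     n_out_of_bounds = unname(removed["out_of_bounds"]),
                     n_retained = nrow(dep$fixes))
  dep
}
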