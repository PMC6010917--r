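#' Default diel activity schedule
#'
#' Hour-of-day speed multipliers emulating the bimodal grazing pattern of
#' rangeland livestock: near rest overnight (22:00-04:00, multiplier 0.1),
#' strong dawn (05:00-09:00) and dusk (16:00-20:00) grazing bouts
#' (multiplier 1.5), moderate activity otherwise (0.7).
#'
#' @return Numeric vector of length 24, one multiplier per local hour 0-23.
#' @export
default_activity_schedule <- function() {
  m <- rep(0.7, 24)
  m[c(23, 24, 1, 2, 3, 4)] <- 0.1   # hours 22,23,0,1,2,3
  m[c(6, 7, 8, 9)] <- 1.5           # hours 5-8
  m[c(17, 18, 19, 20)] <- 1.5       # hours 16-19
  names(m) <- 0:23
  m
}

#' Configure a herd-trajectory simulation
#'
#' The simulated herd centroid follows a correlated random walk (Gaussian
#' turning angles, speed scaled by a diel activity schedule) inside a square
#' fenced pasture with reflecting boundaries; each animal follows a 2-D
#' Ornstein-Uhlenbeck attraction toward the moving centroid: the animal's
#' deviation from the centroid is an OU process with stationary per-axis
#' spread `spread_sd_m`, so every animal travels with the herd while holding
#' a slowly wandering position within it. The activity multiplier scales the
#' OU mean-reversion rate (and with it the step noise) so the stationary
#' spread is the same at all hours while animals settle rather than jitter
#' overnight. GPS observation error is isotropic Gaussian per axis,
#' optionally AR(1)-correlated between consecutive fixes as real receivers
#' are.
#'
#' The simulation runs in a local planar frame whose (0, 0) corner is
#' anchored at a configurable WGS84 origin inside UTM zone 13N, so planar
#' metres and latitude/longitude are interconvertible to projection
#' accuracy.
#'
#' @param n_animals Collared animals per pasture (default 3).
#' @param pasture_side_m Side of the square pasture, metres (default 800,
#'   i.e. 64 ha).
#' @param duration_days Trial length, days (default 7).
#' @param fine_step_s Fine simulation step, seconds (default 1).
#' @param centroid_speed_mean_mps Mean centroid speed before activity
#'   scaling, m/s (default 0.1, giving grazing-season daily travel of a few
#'   kilometres).
#' @param centroid_turn_sd_rad SD of per-step turning angle, radians
#'   (default 0.04; headings persist for roughly twenty minutes, so paths
#'   are locally directed rather than diffusive).
#' @param attraction_rate_per_s OU mean-reversion rate toward the centroid,
#'   1/s (default 2e-5: animals hold their place in the herd over hours).
#' @param spread_sd_m Stationary per-axis SD of an animal about the
#'   centroid, metres (default 25; the mean pairwise distance between two
#'   animals is then `spread_sd_m * sqrt(pi)`).
#' @param activity_schedule Numeric length-24 vector of non-negative
#'   hour-of-day multipliers (default [default_activity_schedule()]).
#' @param gps_sd_m Per-axis isotropic GPS error SD, metres (default 1.634,
#'   which puts the 95% radial error quantile at 4.0 m).
#' @param gps_error_corr_s AR(1) correlation time of the GPS error between
#'   fixes, seconds (default 120; 0 gives independent errors).
#' @param fix_failure_prob Probability a scheduled fix is missed.
#' @param outlier_prob Probability a fix is displaced as an outlier.
#' @param outlier_offset_m Displacement of outlier fixes, metres.
#' @param fix_interval_s Logging cadence, seconds (default 20); must be a
#'   positive multiple of `fine_step_s`.
#' @param start_local Local clock time of simulation start (POSIXct; the
#'   default is a summer midnight).
#' @param utc_offset_hours Local-time offset from UTC (default -6).
#' @param origin_lat,origin_lon WGS84 anchor of the pasture's south-west
#'   corner (default 46.0 N, 102.64 W, western North Dakota, UTM zone 13N).
#' @param seed Integer seed; together with the config it fully determines
#'   the simulation. Random streams are split per animal, so adding an
#'   animal does not change the others' paths.
#' @return A `herd_sim_config` list.
#' @export
herd_sim_config <- function(n_animals = 3L,
                            pasture_side_m = 800,
                            duration_days = 7,
                            fine_step_s = 1,
                            centroid_speed_mean_mps = 0.1,
                            centroid_turn_sd_rad = 0.04,
                            attraction_rate_per_s = 2e-5,
                            spread_sd_m = 25,
                            activity_schedule = default_activity_schedule(),
                            gps_sd_m = 1.634,
                            gps_error_corr_s = 120,
                            fix_failure_prob = 0.02,
                            outlier_prob = 0.001,
                            outlier_offset_m = 5000,
                            fix_interval_s = 20,
                            start_local = as.POSIXct("2017-07-01 00:00:00",
                                                     tz = "UTC"),
                            utc_offset_hours = -6,
                            origin_lat = 46.0,
                            origin_lon = -102.64,
                            seed = 1L) {
  num <- c(pasture_side_m = pasture_side_m, duration_days = duration_days,
           fine_step_s = fine_step_s,
           centroid_speed_mean_mps = centroid_speed_mean_mps,
           centroid_turn_sd_rad = centroid_turn_sd_rad,
           attraction_rate_per_s = attraction_rate_per_s,
           spread_sd_m = spread_sd_m, gps_sd_m = gps_sd_m,
           gps_error_corr_s = gps_error_corr_s,
           fix_failure_prob = fix_failure_prob, outlier_prob = outlier_prob,
           outlier_offset_m = outlier_offset_m,
           fix_interval_s = fix_interval_s,
           utc_offset_hours = utc_offset_hours,
           origin_lat = origin_lat, origin_lon = origin_lon)
  if (any(!is.finite(num)))
    stop("non-finite simulation parameter(s): ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  stopifnot(n_animals >= 1,
            pasture_side_m > 0, duration_days > 0, fine_step_s > 0,
            centroid_speed_mean_mps >= 0, centroid_turn_sd_rad >= 0,
            attraction_rate_per_s >= 0, spread_sd_m >= 0, gps_sd_m >= 0,
            gps_error_corr_s >= 0,
            fix_failure_prob >= 0, fix_failure_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1, outlier_offset_m >= 0,
            fix_interval_s > 0,
            abs(fix_interval_s / fine_step_s -
                  round(fix_interval_s / fine_step_s)) < 1e-9)
  if (length(activity_schedule) != 24 || any(!is.finite(activity_schedule)) ||
      any(activity_schedule < 0))
    stop("activity_schedule must be 24 non-negative finite multipliers")
  structure(list(n_animals = as.integer(n_animals),
                 pasture_side_m = pasture_side_m,
                 duration_days = duration_days, fine_step_s = fine_step_s,
                 centroid_speed_mean_mps = centroid_speed_mean_mps,
                 centroid_turn_sd_rad = centroid_turn_sd_rad,
                 attraction_rate_per_s = attraction_rate_per_s,
                 spread_sd_m = spread_sd_m,
                 activity_schedule = unname(activity_schedule),
                 gps_sd_m = gps_sd_m, gps_error_corr_s = gps_error_corr_s,
                 fix_failure_prob = fix_failure_prob,
                 outlier_prob = outlier_prob,
                 outlier_offset_m = outlier_offset_m,
                 fix_interval_s = fix_interval_s, start_local = start_local,
                 utc_offset_hours = utc_offset_hours,
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 seed = as.integer(seed)),
            class = "herd_sim_config")
}

# reflecting boundary: fold a coordinate into [0, L]
.fold <- function(x, L) {
  p <- x %% (2 * L)
  ifelse(p > L, 2 * L - p, p)
}

# time-varying AR(1)-style recursion x_k = a_k x_{k-1} + u_k, run blockwise
# over runs of constant a_k with stats::filter
.recurse <- function(a, u, init) {
  n <- length(a)
  out <- numeric(n)
  r <- rle(a)
  pos <- 1L
  prev <- init
  for (j in seq_along(r$lengths)) {
    idx <- pos:(pos + r$lengths[j] - 1L)
    out[idx] <- as.numeric(stats::filter(u[idx], r$values[j],
                                         method = "recursive", init = prev))
    prev <- out[idx[length(idx)]]
    pos <- pos + r$lengths[j]
  }
  out
}

#' Simulate herd trajectories
#'
#' Runs the movement model of [herd_sim_config()] at fine temporal
#' resolution and returns every animal's true path together with true daily
#' travel distances (the ground truth against which the logging-scheme
#' estimators are validated).
#'
#' @param config A [herd_sim_config()].
#' @return A `herd_sim` list: `config`; `time_s` (fine-step times from
#'   start); `centroid` (matrix of x, y in pasture metres); `animals`
#'   (list of per-animal position matrices); `truth` (data.frame
#'   `animal_id`, `date_local`, `true_distance_m` -- per-day sums of
#'   fine-step segment lengths over the whole day).
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "herd_sim_config"))
  cf <- config
  dt <- cf$fine_step_s
  L <- cf$pasture_side_m
  n_steps <- as.integer(round(cf$duration_days * 86400 / dt))
  t_step_start <- (seq_len(n_steps) - 1) * dt
  start_secs <- as.numeric(cf$start_local) %% 86400
  hour <- floor(((t_step_start + start_secs) %% 86400) / 3600)
  mult <- cf$activity_schedule[hour + 1]

  set.seed(cf$seed)
  theta <- stats::runif(1, 0, 2 * pi) +
    cumsum(stats::rnorm(n_steps, 0, cf$centroid_turn_sd_rad))
  step_len <- cf$centroid_speed_mean_mps * mult * dt
  cx <- .fold(L / 2 + cumsum(step_len * cos(theta)), L)
  cy <- .fold(L / 2 + cumsum(step_len * sin(theta)), L)
  centroid <- cbind(x = c(L / 2, cx), y = c(L / 2, cy))

  # each animal's deviation from the centroid is an exact-discretised OU
  # process (stationary per-axis SD spread_sd_m), so animals travel with the
  # herd while holding a slowly wandering offset within it
  a <- exp(-cf$attraction_rate_per_s * mult * dt)
  sd_step <- cf$spread_sd_m * sqrt(pmax(0, 1 - a^2))
  animals <- vector("list", cf$n_animals)
  for (i in seq_len(cf$n_animals)) {
    set.seed(cf$seed + i)
    ox0 <- stats::rnorm(1, 0, cf$spread_sd_m)
    oy0 <- stats::rnorm(1, 0, cf$spread_sd_m)
    ox <- c(ox0, .recurse(a, sd_step * stats::rnorm(n_steps), ox0))
    oy <- c(oy0, .recurse(a, sd_step * stats::rnorm(n_steps), oy0))
    animals[[i]] <- cbind(x = .fold(centroid[, 1] + ox, L),
                          y = .fold(centroid[, 2] + oy, L))
  }

  day0 <- floor(as.numeric(cf$start_local) / 86400)
  seg_day <- floor((t_step_start + start_secs) / 86400) +
    (day0 - floor(start_secs / 86400))
  truth <- do.call(rbind, lapply(seq_len(cf$n_animals), function(i) {
    seg <- sqrt(diff(animals[[i]][, 1])^2 + diff(animals[[i]][, 2])^2)
    per <- rowsum(seg, seg_day)
    data.frame(animal_id = sprintf("L%02d", i),
               date_local = as.Date(as.numeric(rownames(per)),
                                    origin = "1970-01-01"),
               true_distance_m = per[, 1])
  }))
  rownames(truth) <- NULL

  structure(list(config = cf, time_s = c(0, t_step_start + dt),
                 centroid = centroid, animals = animals, truth = truth),
            class = "herd_sim")
}

#' @export
print.herd_sim <- function(x, ...) {
  cat(sprintf("Herd simulation: %d animals, %.3g days at %g-s steps, %g x %g m pasture\n",
              x$config$n_animals, x$config$duration_days, x$config$fine_step_s,
              x$config$pasture_side_m, x$config$pasture_side_m))
  invisible(x)
}

#' Observe GPS fixes from one simulated trajectory
#'
#' Samples the true path every `fix_interval_s`, perturbs positions with the
#' configured GPS error model, injects outliers, drops failed fixes, and
#' converts to geographic and UTM coordinates with timestamps. The
#' observation random stream is split per animal and separate from the
#' movement streams.
#'
#' @param sim A [simulate_herd()] result.
#' @param animal Animal index (1-based).
#' @return A time-ordered fix data.frame with columns `logger_id`,
#'   `time_utc`, `time_local`, `lat_dd`, `lon_dd`, `easting_m`,
#'   `northing_m`, `fix_quality`, `satellites`, plus the true planar
#'   positions `x_true`, `y_true`.
#' @export
observe_fixes <- function(sim, animal = 1L) {
  stopifnot(inherits(sim, "herd_sim"), animal >= 1,
            animal <= sim$config$n_animals)
  cf <- sim$config
  step <- as.integer(round(cf$fix_interval_s / cf$fine_step_s))
  idx <- seq(1L, length(sim$time_s), by = step)
  xy <- sim$animals[[animal]][idx, , drop = FALSE]
  ts <- sim$time_s[idx]
  m <- length(idx)

  set.seed(cf$seed + 100000L + animal)
  rho <- if (cf$gps_error_corr_s > 0)
    exp(-cf$fix_interval_s / cf$gps_error_corr_s) else 0
  innov_sd <- cf$gps_sd_m * sqrt(1 - rho^2)
  ex <- as.numeric(stats::filter(stats::rnorm(m, 0, innov_sd), rho,
                                 method = "recursive",
                                 init = stats::rnorm(1, 0, cf$gps_sd_m)))
  ey <- as.numeric(stats::filter(stats::rnorm(m, 0, innov_sd), rho,
                                 method = "recursive",
                                 init = stats::rnorm(1, 0, cf$gps_sd_m)))
  is_outlier <- stats::runif(m) < cf$outlier_prob
  ang <- stats::runif(m, 0, 2 * pi)
  keep <- stats::runif(m) >= cf$fix_failure_prob
  satellites <- sample(6:12, m, replace = TRUE)

  x_obs <- xy[, 1] + ex + ifelse(is_outlier, cf$outlier_offset_m * cos(ang), 0)
  y_obs <- xy[, 2] + ey + ifelse(is_outlier, cf$outlier_offset_m * sin(ang), 0)

  origin <- latlon_to_utm(cf$origin_lat, cf$origin_lon)
  e <- origin$easting_m + x_obs
  n <- origin$northing_m + y_obs
  ll <- utm_to_latlon(e, n)
  time_local <- cf$start_local + ts
  out <- data.frame(logger_id = sprintf("L%02d", animal),
                    time_utc = time_local - cf$utc_offset_hours * 3600,
                    time_local = time_local,
                    lat_dd = ll$lat_dd, lon_dd = ll$lon_dd,
                    easting_m = e, northing_m = n,
                    fix_quality = 1L, satellites = satellites,
                    x_true = xy[, 1], y_true = xy[, 2])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The simulated pasture as a [pasture()] object
#'
#' The square fence of a simulation, in UTM coordinates consistent with the
#' fixes produced by [observe_fixes()].
#'
#' @param config A [herd_sim_config()].
#' @param id,species Pasture metadata.
#' @return A [pasture()].
#' @export
sim_pasture <- function(config, id = "P1", species = "sheep") {
  origin <- latlon_to_utm(config$origin_lat, config$origin_lon)
  L <- config$pasture_side_m
  e0 <- origin$easting_m; n0 <- origin$northing_m
  pasture(id, species,
          rbind(c(e0, n0), c(e0 + L, n0), c(e0 + L, n0 + L), c(e0, n0 + L)))
}

#' Simulate a full multi-animal deployment
#'
#' Convenience wrapper: simulates the herd, observes fixes for every animal,
#' and optionally writes one raw logger file per animal (in the ingest
#' dialect) plus a ground-truth table of true daily distances.
#'
#' @param config A [herd_sim_config()].
#' @param out_dir Optional directory; if given, writes
#'   `<logger_id>.txt` files and `ground_truth.csv` there.
#' @return List with `sim` (the [simulate_herd()] object), `fixes` (named
#'   list of per-animal fix data.frames), `truth` (true daily distances).
#' @export
simulate_deployments <- function(config, out_dir = NULL) {
  sim <- simulate_herd(config)
  fixes <- lapply(seq_len(config$n_animals), function(i) observe_fixes(sim, i))
  names(fixes) <- sprintf("L%02d", seq_len(config$n_animals))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(fixes))
      write_logger_file(fixes[[id]], file.path(out_dir, paste0(id, ".txt")))
    utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(sim = sim, fixes = fixes, truth = sim$truth)
}
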