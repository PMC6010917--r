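#' Daily travel distance from a fix sequence
#'
#' Sums the ellipsoidal geodesic distance between consecutive fixes within
#' each local calendar date. Only segments whose two endpoints share a local
#' date contribute, so the overnight gap between the last evening fix and
#' the next morning's first fix never inflates either day. Days with fewer
#' than two fixes report 0 m and are flagged.
#'
#' @param fixes Time-ordered, daytime-filtered fix data.frame (the logging
#'   scheme, if any, already applied).
#' @return Data.frame with `date_local`, `distance_m`, `n_fixes`,
#'   `hours_covered` (distinct local hours with a fix), `too_few` flag.
#' @export
daily_distance <- function(fixes) {
  if (nrow(fixes) == 0L) {
    return(data.frame(date_local = as.Date(character()), distance_m = numeric(),
                      n_fixes = integer(), hours_covered = integer(),
                      too_few = logical()))
  }
  fixes <- fixes[order(fixes$time_local), , drop = FALSE]
  date <- as.Date(floor(as.numeric(fixes$time_local) / 86400),
                  origin = "1970-01-01")
  rows <- lapply(split(seq_len(nrow(fixes)), date), function(idx) {
    f <- fixes[idx, , drop = FALSE]
    n <- nrow(f)
    d <- if (n < 2L) 0 else
      sum(geodesic_distance_m(f$lat_dd[-n], f$lon_dd[-n],
                              f$lat_dd[-1], f$lon_dd[-1]))
    data.frame(distance_m = d, n_fixes = n,
               hours_covered = length(unique(floor(
                 (as.numeric(f$time_local) %% 86400) / 3600))),
               too_few = n < 2L)
  })
  out <- cbind(date_local = as.Date(names(rows)), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Scheme daily distance as a percentage of constant logging
#'
#' @param scheme_daily,constant_daily Data.frames from [daily_distance()]
#'   for the same deployment (matched on `date_local`, plus `animal_id` if
#'   both carry it). Days where constant logging recorded 0 m are excluded.
#' @return Merged data.frame with a `percent` column
#'   (100 x scheme / constant).
#' @export
percent_of_constant <- function(scheme_daily, constant_daily) {
  keys <- intersect(c("animal_id", "date_local"),
                    intersect(names(scheme_daily), names(constant_daily)))
  if (!"date_local" %in% keys) stop("inputs lack a date_local column")
  m <- merge(scheme_daily[, c(keys, "distance_m")],
             constant_daily[, c(keys, "distance_m")],
             by = keys, suffixes = c("_scheme", "_constant"))
  if (nrow(m) == 0L) stop("no matching deployment-days between inputs")
  m <- m[m$distance_m_constant > 0, , drop = FALSE]
  m$percent <- 100 * m$distance_m_scheme / m$distance_m_constant
  rownames(m) <- NULL
  m
}

#' Mean distance travelled per hour of day
#'
#' Diel activity profile: segments between consecutive same-date fixes are
#' assigned to the local hour of their starting fix, summed per date-hour,
#' then averaged across dates. Used to verify the bimodal
#' (dawn/dusk-grazing) diel structure in both field and simulated data.
#'
#' @param fixes Time-ordered constant-logging fixes of one animal.
#' @return Data.frame with `hour` (0-23) and `mean_dist_m` (NA for hours
#'   never observed).
#' @export
hourly_profile <- function(fixes) {
  out <- data.frame(hour = 0:23, mean_dist_m = NA_real_)
  if (nrow(fixes) < 2L) return(out)
  fixes <- fixes[order(fixes$time_local), , drop = FALSE]
  n <- nrow(fixes)
  secs <- as.numeric(fixes$time_local)
  date <- floor(secs / 86400)
  hour <- floor((secs %% 86400) / 3600)
  seg_ok <- date[-n] == date[-1]
  seg_d <- geodesic_distance_m(fixes$lat_dd[-n], fixes$lon_dd[-n],
                               fixes$lat_dd[-1], fixes$lon_dd[-1])[seg_ok]
  seg_hour <- hour[-n][seg_ok]
  seg_date <- date[-n][seg_ok]
  per <- rowsum(seg_d, group = paste(seg_date, seg_hour))
  ph <- as.integer(sub("^.* ", "", rownames(per)))
  agg <- tapply(per[, 1], ph, mean)
  out$mean_dist_m[match(as.integer(names(agg)), out$hour)] <- as.numeric(agg)
  out
}

#' Fit a multiplicative travel-distance correction factor
#'
#' Underestimated daily distances from a reduced logging scheme are mapped
#' back to the constant-logging scale by a slope beta fitted by Gaussian
#' maximum likelihood: actual = beta x estimated (through the origin by
#' default, since the correction is applied by pure multiplication; an
#' intercept can be added for sensitivity analysis). The 95% CI is a Wald
#' interval from the observed information; a profile-likelihood interval is
#' available.
#'
#' @param estimated Daily distances under the reduced scheme, metres.
#' @param actual Matching constant-logging daily distances, metres.
#' @param intercept Include an intercept term (default FALSE).
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @param conf Confidence level (default 0.95).
#' @param scheme Optional label stored with the model.
#' @return A `correction_model`: list with `beta`, `se`, `ci95`, `sigma`
#'   (residual SD, metres, ML estimate), `alpha` (0 unless `intercept`),
#'   `n`, `scheme`, `intercept`, `loglik`.
#' @export
fit_correction <- function(estimated, actual, intercept = FALSE,
                           ci_method = c("wald", "profile"), conf = 0.95,
                           scheme = NA_character_) {
  ci_method <- match.arg(ci_method)
  ok <- is.finite(estimated) & is.finite(actual)
  x <- estimated[ok]; y <- actual[ok]
  if (length(x) < 3L) stop("need at least 3 (estimated, actual) pairs")
  if (all(x == 0)) stop("degenerate fit: all estimated distances are zero")
  # an exact linear relationship makes the Gaussian likelihood unbounded in
  # sigma; return the exact solution directly
  b0_exact <- sum(x * y) / sum(x * x)
  resid0 <- if (intercept) stats::residuals(stats::lm(y ~ x)) else y - b0_exact * x
  if (max(abs(resid0)) < 1e-9 * max(abs(y), 1)) {
    cf <- if (intercept) stats::coef(stats::lm(y ~ x)) else c(0, b0_exact)
    return(structure(list(beta = unname(cf[2]), se = 0,
                          ci95 = rep(unname(cf[2]), 2), sigma = 0,
                          alpha = unname(cf[1]), n = length(x),
                          scheme = scheme, intercept = intercept,
                          loglik = Inf),
                     class = "correction_model"))
  }
  nll <- function(par) {
    mu <- if (intercept) par[1] + par[2] * x else par[1] * x
    sigma <- exp(par[length(par)])
    -sum(stats::dnorm(y, mu, sigma, log = TRUE))
  }
  b0 <- sum(x * y) / sum(x * x)
  init <- if (intercept) c(0, b0, log(stats::sd(y - b0 * x) + 1e-6))
          else c(b0, log(stats::sd(y - b0 * x) + 1e-6))
  opt <- stats::optim(init, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  bi <- if (intercept) 2L else 1L
  beta <- opt$par[bi]
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc) || vc[bi, bi] < 0) NA_real_ else sqrt(vc[bi, bi])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (ci_method == "wald") {
    c(beta - z * se, beta + z * se)
  } else {
    .profile_ci_beta(nll, opt, bi, conf)
  }
  structure(list(beta = beta, se = se, ci95 = ci,
                 sigma = exp(opt$par[length(opt$par)]),
                 alpha = if (intercept) opt$par[1] else 0,
                 n = length(x), scheme = scheme, intercept = intercept,
                 loglik = -opt$value),
            class = "correction_model")
}

# profile-likelihood CI for the slope: root of the deviance at qchisq(conf, 1)
.profile_ci_beta <- function(nll, opt, bi, conf) {
  target <- opt$value + stats::qchisq(conf, 1) / 2
  prof <- function(b) {
    par <- opt$par
    par[bi] <- b
    keep <- setdiff(seq_along(par), bi)
    o <- stats::optim(par[keep], function(q) {
      p <- par; p[keep] <- q; nll(p)
    }, method = "BFGS")
    o$value - target
  }
  beta <- opt$par[bi]
  step <- max(abs(beta) * 0.5, 0.5)
  lo <- beta - step
  while (prof(lo) < 0) lo <- lo - step
  hi <- beta + step
  while (prof(hi) < 0) hi <- hi + step
  c(stats::uniroot(prof, c(lo, beta))$root,
    stats::uniroot(prof, c(beta, hi))$root)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "Travel-distance correction%s: beta = %.4f (95%% CI %.4f-%.4f), sigma = %.1f m, n = %d\n",
    if (is.na(x$scheme)) "" else paste0(" [", x$scheme, "]"),
    x$beta, x$ci95[1], x$ci95[2], x$sigma, x$n))
  invisible(x)
}

#' Apply a correction model to estimated distances
#' @param model A [fit_correction()] model.
#' @param estimated Estimated daily distances, metres.
#' @return Corrected distances, metres.
#' @export
correct_distance <- function(model, estimated) {
  model$alpha + model$beta * estimated
}

#' Validate a correction factor on held-out data
#'
#' Multiplies held-out estimated distances by the trained correction factor
#' and refits the through-origin model against the held-out constant-logging
#' distances: a slope CI containing 1 means the correction recovers actual
#' daily travel on novel data.
#'
#' @param model A trained [fit_correction()] model.
#' @param estimated,actual Held-out pairs (disjoint from training), metres.
#' @return List with `slope`, `ci95`, `contains_one`, `n`.
#' @export
validate_correction <- function(model, estimated, actual) {
  if (length(estimated) == 0L) stop("empty holdout set")
  corrected <- correct_distance(model, estimated)
  refit <- fit_correction(corrected, actual, intercept = FALSE,
                          scheme = model$scheme)
  list(slope = refit$beta, ci95 = refit$ci95,
       contains_one = refit$ci95[1] <= 1 && 1 <= refit$ci95[2],
       n = refit$n)
}

#' Persist correction models as JSON
#'
#' @param models A single `correction_model` or a list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_correction_models <- function(models, path) {
  if (inherits(models, "correction_model")) models <- list(models)
  doc <- lapply(models, function(m) {
    list(scheme = m$scheme, beta = m$beta, ci95 = m$ci95, sigma = m$sigma,
         n = m$n, intercept = m$intercept, alpha = m$alpha)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read correction models written by [write_correction_models()]
#' @param path JSON path.
#' @return List of `correction_model` objects.
#' @export
read_correction_models <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(m) {
    structure(list(beta = m$beta, se = NA_real_,
                   ci95 = unlist(m$ci95), sigma = m$sigma,
                   alpha = m$alpha, n = m$n,
                   scheme = if (is.null(m$scheme)) NA_character_ else m$scheme,
                   intercept = isTRUE(m$intercept), loglik = NA_real_),
              class = "correction_model")
  })
}
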