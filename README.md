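# herdtrack

Analysis pipeline for high-frequency GPS collar deployments on grazing
livestock. Low-cost collars can log a fix every 20 seconds, but battery
life then caps deployments at about a week; the practical questions are
how few collars suffice to track a herd, and how much is lost when the
logger is duty-cycled. `herdtrack` answers both for datasets in the raw
NMEA logger-file format, and ships a herd-trajectory simulator with known
ground truth so the whole pipeline is testable without field data.

What it does:

- **Ingest & cleaning** — parse header-less logger CSV rows
  (`ddmmyy,hhmmss.sss,quality,ddmm.mmmm,N|S,dddmm.mmmm,E|W,sats`), convert
  NMEA degrees decimal-minutes to decimal degrees and UTM zone 13N
  (NAD83; own Krüger-series transverse Mercator, sub-mm accurate),
  localise timestamps, drop exact duplicates, crop to pasture polygons
  counting removals by reason, and enforce the ≥ 1,000-fix validity rule.
- **Receiver QC** — precision and accuracy as CEP95, the 95% quantile of
  geodesic distances to the unit's fix centroid or to a surveyed
  reference; for isotropic per-axis error σ, CEP95 = σ√(−2 ln 0.05) ≈
  2.4477 σ.
- **Logging schemes** — emulate *regular* (first fix per 5- or 10-min
  clock window) and *burst* (all fixes from the first 5 or 10 min of each
  hour) duty cycles by subsampling constant-logging data; project battery
  life under a duty cycle.
- **Herd dispersion** — per-minute mean pairwise UTM distance among
  collars (first fix per minute per logger; minutes with < 2 valid
  loggers yield no value), with mean / median / 75th-percentile
  summaries.
- **Patch occupancy** — 16-ha quarter and 1-ha grids over each pasture;
  schemes scored by the maximum absolute per-cell occupancy difference
  from constant logging.
- **Travel-distance correction** — daily geodesic travel per scheme;
  multiplicative correction factors `constant = β × estimated` fitted by
  Gaussian maximum likelihood through the origin, Wald or
  profile-likelihood 95% CIs, and held-out validation (corrected slope CI
  containing 1 ⇒ accurate recovery).
- **Simulator** — herd centroid as a correlated random walk with a
  bimodal diel activity schedule inside a reflecting 800 × 800 m pasture;
  each animal's deviation from the centroid is a stationary
  Ornstein–Uhlenbeck offset (mean pairwise distance `spread_sd_m`·√π);
  AR(1) GPS error, fix failures and outliers; writes raw logger files
  round-trippable through the ingest module.

## Worked example

Simulate a week-long three-collar deployment, clean it, and run the three
analyses:

```r
library(herdtrack)

cfg  <- herd_sim_config(seed = 1)          # 3 animals, 7 days, 20-s cadence
dep  <- simulate_deployments(cfg)
past <- list(P1 = sim_pasture(cfg))
fixes <- lapply(dep$fixes, function(f)
  daytime_filter(crop_and_assign(f, past, "P1")))

# herd cohesion: per-minute mean inter-animal distance
dispersion_summary(minute_dispersion(do.call(rbind, fixes)))
#>   n_minutes mean_m p50_m p75_m
#> 1      7560   39.5  36.8  48.3

# patch occupancy error of each reduced scheme (percent, one collar)
occ <- compare_schemes_occupancy(fixes$L01, build_grid(past$P1, "grid_1ha"))
occ[, 3:4] <- round(100 * occ[, 3:4], 2)
occ
#>       scheme    level max_abs_diff mean_abs_diff
#> 1  regular_5 grid_1ha         0.21          0.07
#> 2 regular_10 grid_1ha         0.43          0.13
#> 3    burst_5 grid_1ha         2.00          0.58
#> 4   burst_10 grid_1ha         1.55          0.50

# travel-distance correction for 5-min burst logging
const <- daily_distance(fixes$L01)
b5    <- daily_distance(subsample_burst(fixes$L01, 5))
m <- merge(const[, c("date_local", "distance_m")],
           b5[, c("date_local", "distance_m")],
           by = "date_local", suffixes = c("_const", "_est"))
fit_correction(m$distance_m_est, m$distance_m_const, scheme = "burst_5")
#> Travel-distance correction [burst_5]: beta = 1.8784 (95% CI 1.8138-1.9429), sigma = 371.7 m, n = 7
```

Read: the three collars stayed within ~48 m of each other for 75% of the
daytime period; regular logging reproduces 1-ha patch occupancy to within
half a percent and burst logging to within ~2%; burst logging recovers
only about half the daily travel distance, and multiplying its estimates
by the fitted β ≈ 1.88 maps them back to the constant-logging scale.
Duty-cycle battery arithmetic:

```r
battery_life_projection(171, 7.5)$hours   # 1282.5
battery_life_projection(1306, 1)$days     # 54
```

## Layout

- `R/` — ingest, projection, QC, schemes, dispersion, occupancy,
  correction, simulator
- `tests/testthat/` — unit, property and end-to-end acceptance suites
- `vignettes/logging-intensity-methods.Rmd` — the models, their
  assumptions, and design choices
- `inst/extdata/pastures_synthetic.geojson` — a small synthetic pasture
  boundary fixture (UTM 13N coordinates)
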