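---
title: "Methods: logging intensity, herd cohesion and travel-distance correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logging intensity, herd cohesion and travel-distance correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Low-cost GPS collars on grazing livestock can log a position every 20
seconds, but battery life then limits deployments to about a week. Two
practical questions follow. First, how many collars does it take to know
where a herd is — equivalently, how tightly do herd-mates cluster? Second,
if the logger is duty-cycled to save power — one fix per 5- or 10-minute
window ("regular" logging), or a 5- or 10-minute burst of 20-second fixes
once an hour ("burst" logging) — how much do estimates of patch occupancy
and daily travel distance degrade, and can the travel-distance bias be
corrected?

`herdtrack` implements the full analysis pipeline for such deployments:
raw logger-file ingest and cleaning, receiver QC, scheme emulation by
subsampling, herd-dispersion and patch-occupancy statistics, and
maximum-likelihood correction factors for daily travel distance. Because
collar datasets of this kind are rarely deposited, the package also ships a
herd-trajectory simulator that generates raw logger files with known ground
truth; every downstream stage is validated against it.

# Coordinate handling

Loggers store NMEA degrees decimal-minutes fields (`4916.46,N` means
49° 16.46′ N). `nmea_to_decimal()` converts these to signed decimal
degrees; `decimal_to_nmea()` inverts the encoding (4 decimal-minute digits
by default, a round-trip error below 1e-6°). Planar work uses UTM zone 13N
on NAD83. No projection library is assumed: `latlon_to_utm()` /
`utm_to_latlon()` implement the transverse Mercator by the Krüger series in
the third flattening, truncated at sixth order, whose truncation error is
far below a nanometre; the test suite checks the forward northing against
an independent numerical meridian-arc integral to the millimetre and
round-trips 1,000 random points below 1e-8°. Point-to-point distances are
ellipsoidal geodesics via `geosphere::distGeo()`, the standard choice in
animal telemetry; at pasture scale they agree with planar UTM distances to
better than 0.1%, and the NAD83/WGS84 distinction is far below GPS error.

# Cleaning rules

`ingest_deployment()` applies, in order: malformed-row skipping (field
loggers truncate lines at power loss, so this is never fatal), exact-row
deduplication (stale files from a previous deployment on the SD card),
conversion, cropping to the assigned pasture polygon, and a validity rule.
Cropping counts discards by reason — inside a neighbouring pasture
("wrong side of the fence") versus inside no pasture (transport legs and
satellite-fix outliers) — and the counts telescope exactly to
input − output. A deployment is analysable when it retains at least 1,000
fixes. Analyses use only the daytime window, half-open [04:00, 22:00)
local; the local clock is a fixed integer-hour offset from UTC (default
−6). The fence buffer (default 0 m) can retain fixes within a stated
distance outside the assigned fence, since GPS error near fences is the
usual cause of wrong-side fixes.

# Receiver QC: circular error probability

Precision and accuracy are summarised as CEP95: the empirical 95% quantile
(linear interpolation between order statistics, configurable) of geodesic
distances from each fix to, respectively, the unit's own fix centroid and a
surveyed reference point. For isotropic per-axis Gaussian error σ the
radial error is Rayleigh, so CEP95 = σ√(−2 ln 0.05) ≈ 2.4477 σ; a per-axis
σ of 1.634 m corresponds to a 4.0-m accuracy CEP95 and is the simulator's
default error scale. Across-unit summaries report mean ± SE
(SD/√n units).

# The herd simulator

The herd centroid follows a correlated random walk at a 1-s step: Gaussian
turning increments (SD 0.04 rad/√step, so headings persist for roughly
twenty minutes) and speed `centroid_speed_mean_mps` (default 0.1 m/s)
scaled by an hour-of-day activity multiplier. The default schedule is
bimodal — 0.1 overnight (22:00–04:00), 1.5 in dawn (05:00–09:00) and dusk
(16:00–20:00) grazing bouts, 0.7 otherwise — reproducing the familiar
crepuscular pattern of rangeland livestock. The pasture fence reflects:
coordinates fold back into the square, which keeps occupancy proportions
well defined.

Each animal's deviation from the centroid is a two-dimensional
Ornstein–Uhlenbeck process with stationary per-axis SD `spread_sd_m`
(default 25 m), discretised exactly; the animal therefore travels with the
herd while drifting slowly within it. Two consequences are used as
oracles. The difference of two independent stationary deviations is
Gaussian with per-axis SD s√2, so the pairwise distance between two
animals is Rayleigh with mean s√π — the long-run mean inter-animal
distance is checked against this closed form within three batch-means
Monte-Carlo standard errors. And the activity multiplier scales the OU
*rate* (and with it the step noise), so the stationary spread is identical
at all hours: animals settle overnight rather than jitter, without
changing the cohesion law.

Observation takes every 20th second of truth, adds isotropic Gaussian GPS
error (per-axis σ 1.634 m), drops fixes with probability 0.02, and
displaces outliers (probability 0.001) by 5 km — far enough that the
cleaning stage removes them, as transport legs and bad fixes are removed
from real data. GPS error is AR(1)-correlated between consecutive fixes
(default correlation time 120 s) because receiver error is strongly
autocorrelated at a 20-s cadence; the stationary marginal is unchanged, so
CEP calibration is unaffected, while consecutive-fix error differences are
realistic rather than white. Random streams are split per animal: adding a
collar never changes the other animals' paths.

Defaults were calibrated once to the headline behaviour of week-long
cattle/sheep deployments on 800 × 800 m (64 ha) rangeland pastures: daily
travel of a few kilometres under constant logging, mean inter-animal
distances of tens of metres, regular-logging distance recovery of roughly
75–80% of constant logging and burst recovery near 55%, and occupancy
differences under ~2%. What the simulator does *not* emulate: behavioural
states (grazing/resting/travelling as discrete modes), forage or terrain
covariates, fence-line tracking, satellite-geometry (DOP) structure in the
error, or fix re-acquisition delay after a power-off period. Passing tests
therefore show the estimators are correct for a cohesive, diel-modulated
random-walk herd — not that any particular field dataset satisfies those
assumptions.

# Logging schemes

Subsampling emulates reduced logging exactly as a duty-cycled logger would
behave. Windows are clock-aligned and half-open (a 5-min window starts at
:00, :05, …); `subsample_regular()` keeps the first fix per window,
`subsample_burst()` keeps all fixes in the first `interval` minutes of
each hour (phase configurable). Both return order-preserving subsequences,
which yields two structural guarantees asserted on every simulation run:
scheme daily distance can never exceed constant-logging distance (triangle
inequality), and regular(5) distance is at least regular(10) distance on
aligned windows. `battery_life_projection()` is the duty-cycle arithmetic
(base hours × extension factor, with whole-day reporting).

# Dispersion, occupancy, distance

Herd dispersion uses the first fix per local minute per logger (so the
phase of a 20-s cadence within the minute cannot inflate distances), then
the mean pairwise planar UTM distance per minute among loggers — three
loggers give the mean of three pairwise distances, two give their
distance, fewer give no value. Summaries report the mean, median and 75th
percentile of the per-minute series.

Patch occupancy tiles the pasture bounding box, anchored at its minimum
corner: four equal quarters (~16 ha) or 100 × 100 m (1-ha) cells, clipped
to the boundary. Cells are half-open so a boundary fix belongs to exactly
one cell (points exactly on the bounding-box maximum edge fold into the
last cell). Schemes are scored per deployment by the per-cell absolute
difference in proportions against constant logging, reported
conservatively as the maximum across cells (the mean is also given), then
averaged across deployments. Note that coarsening is not monotone: a
quarter's difference is the sum of its nested 1-ha signed differences, so
it can exceed the largest 1-ha difference; the tests assert the correct
nesting bound (|quarter Δ| ≤ Σ nested |1-ha Δ|).

Daily travel distance is the sum of geodesic segments between consecutive
fixes sharing a local date, after daytime filtering; the overnight gap
never contributes. Days with fewer than two fixes report 0 m and are
flagged, and a minimum-coverage filter (≥ 12 daytime hours with fixes) is
applied before any regression.

# Travel-distance correction

Reduced schemes cut corners, so their daily distances underestimate the
20-s reference. The correction model is multiplicative:
constant = β × estimated, fitted by Gaussian maximum likelihood through
the origin (`fit_correction()`), because the correction is applied by pure
multiplication; an intercept option exists for sensitivity analysis. The
95% CI is the Wald interval from the observed information (a
profile-likelihood option is available and agrees closely away from
degenerate fits; an exactly proportional dataset is returned as the exact
solution, since the likelihood is then unbounded in σ). Validation
multiplies held-out estimated distances by the trained β and refits: a
slope CI containing 1 indicates the correction recovers actual travel on
novel data.

Two design choices matter here. First, regression pairs are pooled to
pasture-day means before fitting: the collars in one pasture share a
single herd trajectory, so their daily ratios are strongly correlated and
animal-days would be pseudo-replicates; the day is the independent unit.
Second, the end-to-end recovery study trains on three simulated 7-day
months and validates on a held-out fourth, mirroring a season in which the
first month is reserved as novel data.

A caution the package's own tests quantify: the corrected slope is the
ratio of two fitted slopes, so its sampling dispersion is
√(1 + n_holdout/n_train) times the holdout standard error that the refit's
Wald CI measures. With a fixed 3:1 train:holdout design the nominal 95%
interval can cover the corrected slope at most about 91% of the time per
scheme, and the event that all four schemes' intervals simultaneously
contain 1 occurs less often still (about half of seeds under the default
conditions, where day-level herd-common variation also narrows the
small-sample ML interval). Point recovery is excellent — corrected slopes
centre tightly on 1.0 — but the nominal holdout CI should be read as a
description of the refit, not as a calibrated 95% statement about the
correction factor. A practitioner wanting calibrated uncertainty should
propagate the training-fit variance as well.

# Numerical and degenerate-input choices

Quantiles default to linear interpolation between order statistics
(configurable). Window widths must divide 60 minutes; timestamp ties break
by input order. Empty inputs error early with a message naming the
operation (empty fix sets for centroid/CEP/occupancy, empty dispersion
series, empty holdout). Exact duplicate rows only are deduplicated — two
fixes with one timestamp but different coordinates are both kept.
Through-origin fits reject an all-zero predictor. The simulator validates
finiteness and sign of every parameter and requires the fix interval to be
a multiple of the fine step.

# Problem sizes

The shipped tests use, by choice: a 7-day, 3-animal default simulation at
a 1-s fine step for the scheme comparisons; four 7-day months (and 50
replicate four-month seasons) for the correction-recovery study; 10,000
fixes for CEP calibration; and 1-day, 5-s-step runs for cohesion
calibration. These match the scale of the week-long field deployments the
pipeline is designed around.
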