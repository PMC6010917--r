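Package: herdtrack
Title: Processing and Logging-Intensity Analysis of High-Frequency Livestock GPS Collar Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with high-frequency (20-second) GPS collar data from
    grazing livestock herds. Parses raw NMEA-style logger files, converts degrees
    decimal-minutes coordinates to decimal degrees and UTM (zone 13N, NAD83),
    cleans deployments (deduplication, pasture cropping, minimum-fix validation),
    quantifies receiver precision and accuracy as 95% circular error probability,
    emulates reduced logging schemes (regular and burst duty cycles) by
    subsampling, measures herd cohesion as per-minute mean inter-animal distance,
    compares patch occupancy across logging schemes, and fits maximum-likelihood
    multiplicative correction factors for the underestimation of daily travel
    distance. Includes a herd-trajectory simulator (correlated random walk
    centroid with Ornstein-Uhlenbeck attraction per animal) that provides ground
    truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
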