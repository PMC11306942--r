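Package: stepconcord
Title: Agreement Analysis for Paired Wearable Step-Count Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for method-comparison analysis of daily and hourly
    step counts recorded simultaneously by a hip-worn research accelerometer
    (30-second epochs) and a wrist-worn consumer device (hourly totals) in
    free-living settings. Covers wear-time harmonization (Choi nonwear
    detection, daily possible-wear windows, valid-day rules), construction of
    same-date person-day and trimmed overlap-block person-hour analysis
    samples, and the full agreement-statistics suite: intraclass correlation,
    Lin's concordance correlation, repeated-measures Bland-Altman limits of
    agreement on absolute and percent scales, tolerance-band agreement, and
    Cohen's kappa at steps-per-day thresholds, plus covariate-adjusted
    regression slopes and interaction tests with cluster-robust errors.
    Includes a synthetic paired-cohort generator with known ground truth and
    analytic recovery oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
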