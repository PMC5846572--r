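Package: gvp
Title: Glycemic Variability Percentage and Companion Metrics for
    Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computes the glycemic variability percentage (GVP), the
    normalized arc length of a continuous glucose monitoring (CGM) trace,
    together with the classic comparison metrics: standard deviation,
    coefficient of variation, distance traveled, mean absolute glucose
    change (MAG), CONGA, and MAGE.  Includes CSV import and export with
    gap detection and resampling, square-wave and synthetic-cohort
    simulators, cohort percentile summaries, and a four-level
    classification of glycemic variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
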