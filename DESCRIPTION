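Package: agpkit
Title: Ambulatory Glucose Profile Metrics, Synthetic CGM Cases, and
    Rule-Based Summarization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing continuous glucose monitor (CGM) time
    series on the Ambulatory Glucose Profile (AGP) framework: reading and
    regularizing two-column CGM exports, the ten standard AGP summary
    metrics (time in ranges under both the cumulative and the banded
    level-1 convention, Glucose Management Indicator, coefficient of
    variation), time-of-day percentile bands, consensus-based episode
    detection, and deterministic rule-based renderings of the five AGP
    summarization tasks (data quality, hyperglycemia, hypoglycemia,
    variability, main clinical concern).  A seeded synthetic-case
    generator built on a Bergman-type glucose-insulin minimal model
    produces 14-day type 1 diabetes cases calibrated to a prescribed
    Glucose Management Indicator, and a grading module scores binary
    clinician rubric answers and computes Gwet's AC1 chance-corrected
    inter-rater agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
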