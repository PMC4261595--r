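Package: sepscreen
Title: Electronic Sepsis Screening Alerts for Emergency Department Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replays time-stamped emergency-department patient event streams
    (vitals, labs, therapy orders, code status) through a rule-based severe
    sepsis and septic shock screening alert built from SIRS and
    therapy-conditional organ-dysfunction criteria, with alert-suppression
    windows to limit repeat activations. Includes patient-level diagnostic
    accuracy evaluation (sensitivity, specificity, predictive values,
    likelihood ratios with exact and score confidence intervals, alert-to-ICU
    lead time) and a seeded synthetic ED cohort simulator with calibration of
    stratum severity to target alert rates, so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
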