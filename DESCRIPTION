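Package: chronomeal
Title: Meal Timing Relative to the Sleep/Wake Cycle and Cardiometabolic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives chrononutrition exposures (eating window, caloric
    midpoint, eating jetlag, and intervals anchored on the midsleep point)
    from 24-hour dietary recall event tables and actigraphy-derived sleep
    summaries, applies the dual-entry coefficient-of-variation
    reconciliation rule and actigraphy validity filters, computes
    cardiometabolic markers including a sex-stratified composite risk
    Z-score (waist, blood pressure, glucose, HDL-C sign-flipped,
    triglycerides), and runs the sex-stratified standardized-beta
    regression layer with Benjamini-Hochberg or Hochberg multiplicity
    control. Ships a seeded synthetic-cohort generator with planted
    sex-specific effects so the full pipeline can be exercised and
    validated without access to participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
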