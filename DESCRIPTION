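Package: smokelink
Title: Wildfire Smoke Exposure Attribution and Health-Related Quality of
    Life Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking episodic wildfire-smoke exposure to
    health-related quality-of-life outcomes in cohort studies. Classifies
    smoke days from satellite-detected plume polygons intersected with a
    study area, attributes smoke PM2.5 and black carbon by deviation of
    smoke-day concentrations from same-calendar-month non-smoke-day
    medians pooled over three years (zero-truncated), builds multi-window
    (7/15/30/60-day) exposure metrics for subject visits, scores the St
    George's Respiratory Questionnaire and SF-36 (including a fixed
    simple-structure two-factor reduction of the eight SF-36 domains),
    and fits covariate-adjusted linear association, interaction and
    sensitivity models. Includes a synthetic-data generator with known
    ground truth (plume calendars, gridded pollutant fields, a smoker
    cohort, planted exposure effects) so every stage is testable without
    access to restricted cohort or air-quality data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
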