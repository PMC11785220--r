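Package: somna
Title: Actigraphy Sleep Scoring, Regularity, and Light-Exposure Analysis for Community Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for wrist-actigraphy field studies of sleep
    across living environments and seasons: epoch-level sleep/wake scoring with
    an open weighted-window algorithm, nightly rest-interval detection,
    diary-based quality-control filters, circular statistics for clock-time
    parameters, the Sleep Regularity Index, 24-hour activity waveforms,
    50-lux light-exposure metrics, and a group-comparison layer
    (per-season linear models against a housed reference, one-way ANOVA with
    many-to-one Dunnett contrasts, Bartlett variance tests, chi-squared tests
    on sleepless nights, linear mixed models for light timing with Tukey
    post-hocs, and two-way mixed ANOVA on waveforms). Includes a seeded
    synthetic-cohort generator with photoperiod-driven light exposure so the
    full pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    multcomp,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
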