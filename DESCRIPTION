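Package: affectfanova
Title: Functional ANOVA for Continuous Valence-Arousal Rating Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing continuous two-dimensional emotion-space
    (valence/arousal) rating curves collected at 1 Hz while participants
    listen to music or speech. Provides normalization and grid validation,
    per-second mean curves and quadrant classification, time-series
    inter-rater reliability screening via Cronbach's alpha, questionnaire
    scoring (TIPI Big-Five, TEIQue-SF trait emotional intelligence, mood
    semantic differentials) with z-score mean-split grouping, a
    heteroscedasticity-robust functional analysis of variance based on a
    Cramer-von Mises statistic between locally-polynomial-smoothed group
    mean curves calibrated by functional bootstrap, a full
    stimulus-by-dimension-by-factor test battery with Benjamini-Hochberg
    false discovery rate control, and a synthetic-study generator with
    AR(1) participant noise and localized group effects for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
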