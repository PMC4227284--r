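Package: wardscores
Title: Severity Scores and Deterioration Risk Analysis for Hospital Ward Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a nested case-control analysis of clinical
    deterioration among non-ICU ward patients admitted with infection.
    Provides a synthetic ward-EHR cohort generator with known ground truth;
    calculators for nine severity-of-illness scores (SOFA, APACHE II,
    SAPS II, MEWS, ViEWS, REMS, MEDS, PIRO, SCS) driven by auditable
    band-table fixtures; pre-event time-window feature extraction with a
    carry-back / assume-normal imputation cascade; risk-set sampling of
    admission-date-matched controls; and evaluation machinery including
    DeLong ROC analysis, Youden-index threshold selection, derivation of a
    two-threshold decision rule on the earliest SOFA score and its change
    over time, adjusted odds ratios, and mixed-effects score trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2
Config/testthat/edition: 3
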