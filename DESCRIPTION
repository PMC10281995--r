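Package: rhipem
Title: Position-Exposure Matrices and Cumulative Head Impact Indices for
    Repetitive Head Impact Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for retrospective reconstruction of repetitive head
    impact (RHI) exposure in American football.  Builds position-exposure
    matrices (PEMs) from study-level helmet-sensor summaries using
    sample-size-weighted pooling, with group expansion, missing-cell
    imputation and level-of-play mapping; computes per-athlete cumulative
    head impact indices (CHII, CHII-G, CHII-R) from season-by-season
    career histories; and fits the exposure-to-neuropathology association
    battery (age-adjusted logistic and linear regressions with scaled
    effect units, BIC evidence categories, bootstrap ROC comparison and
    10-fold cross-validation).  A seeded synthetic-cohort generator
    emulates the structure of football brain-donor cohorts so the whole
    pipeline is testable without restricted donor data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
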