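Package: moodscreen
Title: Depression Screening from Daily Mobile Mental-Health Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening depression from daily self-reported
    mental-health ratings (sleep dissatisfaction, mood, anxiety) collected
    by mobile mental-health trackers. Daily ratings are collapsed into
    biweekly indicator variables by three data-processing approaches
    (average, ratio, frequency), screened against biweekly PHQ-9 outcomes
    with a random-intercept logistic panel model estimated by Gauss-Hermite
    quadrature, and evaluated by tie-aware ROC/AUC analysis with
    DeLong-type chi-square comparison tests and five-fold cross-validation.
    Per-item dichotomization cut-offs are chosen by an AUC-maximizing
    search. Patient adherence to self-reporting is quantified on four
    dimensions (activeness, timeliness, duration, persistence), clustered
    by k-means, and linked to screening accuracy. A seeded synthetic-cohort
    generator emulates the longitudinal reporting process (patient
    heterogeneity, reporting gaps, delayed reports, dropout) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
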