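Package: forumlot
Title: Lines of Therapy from Patient-Forum Posts with EMR/Claims Cohort Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives per-patient lines of systemic therapy for advanced melanoma
    from free-text patient-forum posts and compares the resulting treatment-pattern
    estimates against EMR/claims-style comparator cohorts. Includes a seeded
    synthetic-cohort generator (ground-truth patient journeys rendered as noisy
    forum posts and comparator tables), text cleaning and sentence tokenization,
    a brand/generic/typo-tolerant treatment lexicon, a TF-IDF sentence classifier
    (linear SVM, multinomial naive Bayes, KNN), rule-based negation detection and
    temporal-expression resolution, a line-of-therapy assignment algorithm with
    combination and adjuvant rules, 4:1 frequency matching on first-line year, and
    Wald 95% confidence-interval overlap concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
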