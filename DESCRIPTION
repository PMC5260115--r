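Package: fuzzymcda
Title: Fuzzy Multi-Criteria Decision Analysis with Buckley AHP and Fuzzy TOPSIS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group multi-criteria decision analysis under linguistic
    uncertainty, built around triangular fuzzy numbers. Implements Buckley's
    geometric-mean fuzzy Analytic Hierarchy Process (AHP) for deriving
    criterion weights from reciprocal pairwise-comparison matrices over a
    two-level criteria hierarchy, Saaty-style consistency checking, fuzzy
    TOPSIS ranking of alternatives from linguistic expert ratings, and
    expert-weighting sensitivity analysis. Ships the complete worked study
    of anesthesia-method selection for circumcision surgery (three expert
    pediatric surgeons, four main criteria, eight sub-criteria, three
    alternatives) as a packaged fixture, together with a synthetic
    expert-panel generator with known ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
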