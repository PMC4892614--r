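Package: fuzzystage
Title: Neuro-Fuzzy Prediction of Prostate Cancer Pathological Stage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether prostate cancer is organ-confined or
    extra-prostatic at pathology from five pre-treatment clinical variables
    (biopsy primary and secondary Gleason patterns, PSA, age at diagnosis and
    clinical T stage). Implements fuzzy c-means clustering, a cluster-seeded
    Takagi-Sugeno-Kang fuzzy inference system with Gaussian membership
    functions tuned by hybrid adaptive neuro-fuzzy (ANFIS) training, the AJCC
    2010 anatomic stage/prognostic group nomogram as a clinical baseline, the
    categorical grouping scheme for the clinical inputs, a seeded synthetic
    cohort generator matching the study dataset's published margins, and a
    ROC / McNemar evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
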