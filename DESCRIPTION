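Package: aminoscreen
Title: Plasma Amino-Acid Profiling and Matched Case-Control Screening
    Models for Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating plasma free amino-acid
    ("aminogram") screening classifiers with a matched case-control design.
    Provides a seeded multivariate-normal cohort generator calibrated to
    published group-wise concentration summaries, greedy age/gender/smoking
    matching at a fixed case:control ratio, univariate profiling
    (Mann-Whitney tests, per-analyte ROC areas), principal component
    analysis of standardized aminograms with contributor extraction,
    exhaustive best-subset unconditional logistic regression scored by a
    leave-one-out cross-validated information criterion, conditional
    logistic regression over matched strata with a logit discriminant
    score, and ROC/subgroup evaluation, plus an end-to-end reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
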