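Package: smokesig
Title: Inference of Tobacco Smoking Habits and History from Blood DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates classifiers of tobacco smoking habit and
    history from blood DNA methylation beta values. Provides candidate-marker
    ascertainment from epigenome-wide association evidence, participant
    quality control, binary and multinomial logistic models, backward
    marker elimination with a likelihood-ratio stopping rule, cumulative
    AUC profiling, fivefold cross-validation and bootstrap optimism
    correction, threshold-based inference of cessation time and pack-years,
    comparison against a plasma cotinine cut-off, and application of frozen
    adult models to newborn and childhood cohorts. Includes a synthetic
    methylation cohort generator so every stage is testable without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
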