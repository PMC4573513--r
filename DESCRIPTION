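Package: shiftjem
Title: Probability-Based Shift-Work Job-Exposure Matrix and Weight-Status
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a probability-of-shift-work job-exposure matrix from
    labour-survey records tabulated by sex and hierarchical occupation code,
    with small-cell confidentiality suppression and specific-to-broad code
    fallback; links the matrix to study participants, categorizes exposure,
    computes and trims body mass index, selects confounders by the 10%
    change-in-estimate criterion, and fits baseline-category multinomial
    logistic regression of weight class on shift-work exposure. Includes a
    synthetic-data generator emulating the labour survey and study samples
    so every stage is testable end to end, plus a misclassification
    (attenuation) simulation for group-level exposure probabilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
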