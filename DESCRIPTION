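Package: mrmcboot
Title: Multireader Multicase ROC Analysis with Two-Way Clustered Bootstrap
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for fully crossed multireader multicase (MRMC)
    diagnostic-accuracy studies with ordinal BI-RADS assessments and
    conditional probability-of-malignancy (POM) ratings. Computes empirical
    (trapezoidal / tie-corrected Mann-Whitney) ROC curves and AUCs per
    reader and reading mode, compares reading modes with a random-reader
    random-case two-way bootstrap (patient-clustered case resampling crossed
    with reader resampling, percentile confidence intervals and bootstrap P
    values), and derives sensitivity and specificity at the BI-RADS 4-5
    positivity rule overall and within breast-density and lesion-type
    strata. A latent-score variance-components simulator in the Roe-Metz
    tradition generates complete synthetic reader studies with exact case
    composition and calibrated per-mode discriminability, so every stage of
    the pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
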