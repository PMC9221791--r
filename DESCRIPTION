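Package: perirad
Title: Intra- and Peritumoral CT Radiomics for Two-Year Recurrence-Free
    Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomics analysis of 2-D chest CT slices for predicting
    two-year recurrence-free survival in resected non-small cell lung
    cancer. Builds intratumoral, size-variant peritumoral (3-30 mm in 3 mm
    steps, by morphological dilation with chest-wall and airway exclusion)
    and combined region masks; extracts a 69/58/127-feature panel of
    intensity, GLCM, GLRLM, LBP and shape features; selects features by
    neighborhood component analysis with incremental AUC-maximising subset
    search; classifies patients with RBF-kernel SVM and 60-tree random
    forests under stratified cross-validation; and summarises outcomes
    with Kaplan-Meier curves, log-rank tests and DeLong AUC comparisons.
    Includes a synthetic CT-phantom cohort generator so the full pipeline
    is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    randomForest,
    survival,
    jsonlite,
    RNifti,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
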