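Package: aqindex
Title: Amyloid Quantification Index for Dynamic PiB PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free quantification of amyloid burden from the first
    30 minutes of a dynamic 11C-PiB PET scan. Implements the two-slope
    amyloid quantification index (AQI) on region time-activity curves, its
    late-window comparators (SUVR and reference-region Logan DVR), grid
    search optimization of the index parameters, lasso-based selection of
    featured brain regions with a z-scored linear combination into a
    subject-level index, and a classification and statistics harness
    (stratified cross-validated logistic regression, ROC analysis with
    Youden thresholds, effect sizes, Kruskal-Wallis tests and clinical-score
    correlations). A kinetic simulator (tri-exponential arterial input,
    one-tissue reference region, SRTM target regions) generates synthetic
    cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
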