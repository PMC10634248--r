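Package: immunoprof
Title: Immune Activation Profiling and Neurocognitive Biomarker Screening
    for HIV Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse panels of peripheral-blood immune activation
    markers (T-cell, NK-cell, monocyte, inflammation and endothelial
    markers) in cohorts of people living with HIV.  Implements marker-level
    quality control (missingness filtering, two-nearest-neighbour mean
    imputation, correlation-based deduplication), non-parametric screening
    against neurocognitive impairment with Benjamini-Hochberg FDR control,
    linear discriminant classification evaluated by repeated stratified
    two-fold cross-validation, genetic-algorithm selection of parsimonious
    marker subsets, double hierarchical (Ward) clustering of patients and
    markers into immune activation profiles with Hopkins, silhouette and
    gap-statistic diagnostics, and profile-outcome enrichment statistics
    (Fisher tests, odds ratios).  A calibrated synthetic-cohort generator
    reproduces the statistical structure of such cohorts so that every
    stage can be exercised and validated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
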