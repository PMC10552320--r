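Package: methpanel
Title: Serum cfDNA Methylation Biomarker Discovery, Prioritization and
    Validation for Colorectal Advanced Neoplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for blood-based DNA methylation
    biomarker development built around a pooled-array design: stratified
    cohort splitting and sex-balanced cfDNA pool construction, epigenome-wide
    differential methylation on pooled beta-values with empirical-Bayes
    moderated t-statistics and Benjamini-Hochberg FDR control, annotation
    enrichment against the array background, candidate prioritization by a
    statistically-equivalent-signatures search with cross-validated ranking
    over logistic, random-forest and support-vector learners, penalized
    (lasso / elastic-net) panel selection on pyrosequencing percent
    methylation, and validation by leave-one-out cross-validated ROC with
    Youden cutoffs and exact binomial confidence intervals. Includes a
    synthetic-data generator that emulates two-class serum methylomes with
    planted differentially methylated positions, ten-member sex-balanced
    pools, array and pyrosequencing measurement noise, concordant bisulfite
    sequencing tables, non-colorectal tumor sera and matched serum/plasma
    pairs, so the full pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
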