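Package: metamced
Title: Two-Tier Serum Metabolomics Multi-Cancer Detection and
    Tissue-of-Origin Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-cancer early detection (MCED) from
    untargeted LC-MS serum metabolomics. Aligns per-sample peak lists into a
    feature matrix using virtual-lock-mass (VLM) ppm mass windows anchored on
    a metabolite reference, applies the preprocessing stack (prevalence
    filtering, reference-based quantile normalization usable one sample at a
    time, log10 transform, standard scaling, k-nearest-neighbour imputation
    with a selective per-class policy), reduces features by PLS-DA, and fits
    a two-tier classifier: a binary cancer-detection linear score (CDAI) with
    threshold-zero decision and repeated random-split cross-validation, and a
    one-vs-rest multiclass tissue-of-origin model (TOOAI) with top-2
    (double-class) prediction accuracy. Includes a synthetic cohort generator
    with class-specific intensity shifts, ppm-scale mass error, batch drift
    and dropout; recursive feature elimination ranking; confusion-count
    metrics with percentile confidence intervals; ROC-AUC; and a repeated-run
    robustness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    e1071,
    mixOmics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
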