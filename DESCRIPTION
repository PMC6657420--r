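Package: alterex
Title: Predicting Genomic Alterations from Gene Expression with Gene
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Binary classification of gene-level somatic alterations
    (mutations, amplifications, deletions) from bulk and single-cell gene
    expression profiles. Provides the full benchmarking framework: a
    synthetic cohort simulator with negative-binomial counts, regulon
    co-expression structure and planted driver/passenger alterations;
    CNV segment-to-gene assignment and event-matrix construction with the
    standard frequency filters; expression normalization and covariate
    regression; two gene-aggregation strategies (signed regulon activity
    scores and Tukey-biweight cluster averages); two information-reduction
    engines (Gaussian noise addition and beta-distributed read
    down-sampling with dropout); a per-event gradient-boosting modeling
    harness with repeated train/test partitions; and AUROC-based
    evaluation with paired Wilcoxon model comparison and robustness
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    ranger,
    class,
    glmnet,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
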