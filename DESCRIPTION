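Package: epiholdout
Title: Leakage-Corrected Benchmarking of Enhancer-Promoter Interaction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking enhancer-promoter interaction (EPI)
    classifiers under chromosome-held-out evaluation, where whole chromosomes
    are assigned to training, validation and test partitions so that enhancers
    or promoters reused across candidate pairs can never leak between
    partitions. Provides a synthetic EPI data generator with planted
    epigenomic signal, class imbalance, element duplication and an optional
    element-memorization leak; window extraction and sliding-window
    summarization of per-base epigenomic tracks into CNN-format tensors and
    TargetFinder-format region means; one-hot sequence encoding; a declarative
    model zoo of one-dimensional convolutional, attention, residual and
    feed-forward architectures with exact per-layer parameter accounting; an
    imbalance-aware training engine (weighted binary cross-entropy, Adam,
    early stopping on validation F1); and chromosome-sweep evaluation with
    sample-size-weighted AUROC aggregation and paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    pROC,
    knitr,
    rmarkdown
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
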