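Package: cellbridge
Title: Cross-Domain Transfer Learning for Predicting Molecular Measurements
    from Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts molecular measurements (metabolite abundance, protein
    expression, copy-number, gene-dependency, drug-sensitivity and mutation
    status) of cancer cell lines from bulk gene expression alone, by
    transferring representation learned on a large tumor transcriptome
    domain to a small cell-line domain. Implements per-gene two-sample
    Kolmogorov-Smirnov feature selection to avoid negative transfer,
    two-step autoencoder pre-training with encoder weight transfer and
    full fine-tuning, a penalized-regression / random-forest baseline
    suite, a five-fold cross-validation benchmarking harness with
    confidence-interval aggregation, drug-screening selectivity analysis,
    and a latent-factor synthetic two-domain generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
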