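Package: grmfc
Title: Graph-Regularized Matrix Factorization for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions by non-negative matrix
    factorization with graph dual regularization on drug and target similarity
    manifolds and a hard consistency constraint that pins known interactions,
    solved by an alternating-direction (augmented-Lagrangian) algorithm with
    closed-form block updates. Includes p-nearest-neighbor graph sparsification
    and normalized Laplacians, readers for tab-delimited interaction and
    similarity matrices, a seeded synthetic-data generator with planted
    low-rank structure, cold-start cross-validation (drug-wise and target-wise
    fold masking) with AUC/AUPR metrics and grid search, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
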