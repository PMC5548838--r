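Package: lrlshmda
Title: Laplacian Regularized Least Squares for Microbe-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised link prediction on bipartite microbe-disease
    association networks. Computes Gaussian interaction profile kernel
    similarities for microbes and diseases from a 0/1 association matrix,
    fits closed-form Laplacian regularized least squares classifiers in
    both spaces, and fuses them into scores for every microbe-disease
    pair. Includes per-disease candidate ranking, global and local
    leave-one-out cross validation with per-run kernel recomputation,
    repeated k-fold cross validation, ROC/AUC evaluation with the midrank
    tie convention, synthetic bipartite network generators for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    tibble,
    utils,
    stats,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
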