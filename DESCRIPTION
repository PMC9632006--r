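Package: cdaboost
Title: circRNA-Disease Association Prediction with Boosted-Tree Leaf Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts circRNA-disease associations from a heterogeneous network.
    Builds integrated circRNA and disease similarity matrices from expression-profile
    Pearson similarity, precomputed disease semantic similarity, and Gaussian
    interaction profile (GIP) kernels on the binary association matrix; extracts
    per-pair statistical, graph-centrality, top-k-neighbour and non-negative matrix
    factorization (NMF) features; derives one-of-K leaf-membership embeddings from a
    first gradient-boosted tree model; and trains a final boosted classifier
    evaluated by stratified k-fold cross-validation with balanced negative sampling.
    Includes a synthetic block-structured data generator so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    methods,
    Matrix,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
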