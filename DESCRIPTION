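Package: gonnmda
Title: Ordered Message-Passing Graph Neural Networks for miRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA-disease associations by fusing multi-source
    similarity matrices (disease semantic similarity over MeSH-style DAGs,
    Gaussian interaction-profile kernels, miRNA functional and
    Needleman-Wunsch sequence similarity) through truncated singular value
    decomposition, learning node embeddings on a typed heterogeneous
    biomolecular graph with an ordered (gated, root-tree aligned)
    message-passing network that resists over-smoothing, and scoring
    candidate pairs with a multilayer perceptron under stratified k-fold
    cross-validation. Includes a planted-partition synthetic data generator
    for desk-scale benchmarking without any database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
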