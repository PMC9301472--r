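Package: severityNet
Title: Sparse Hierarchical Graph Representation Learning for
    Connectome-Based Severity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts continuous symptom-severity scores from functional
    brain connectivity matrices with a sparse hierarchical graph neural
    network. Provides connectome construction (Pearson and
    Tikhonov-regularized partial correlation, proportional thresholding,
    per-subject standardization, covariate residualization), an
    edge-to-edge/edge-to-node feature extractor feeding self-attention
    top-k graph pooling with three adjacency-embedding variants, an SGD
    cross-validation training harness with cosine learning-rate
    annealing, eight graph-theoretic nodal measures, a three-level
    canonical correlation analysis relating learned node embeddings to
    those measures, gradient-saliency edge attribution, and a seeded
    synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
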