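Package: cytonet
Title: Regularized Cytokine-Symptom Network Analysis with Stability and
    Comparison Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation and comparison of regularized partial-correlation
    networks for cytokine and symptom data from clinical cohorts. Implements
    Spearman rank correlation input with positive semi-definite repair,
    graphical LASSO estimation with Extended Bayesian Information Criterion
    (EBIC) model selection, strength centrality and influential-node
    selection, signed spinglass community detection with median-consensus
    seeding, nonparametric and case-dropping bootstrap stability analysis
    (edge inclusion proportions and the CS-coefficient), and permutation
    based network comparison tests (global strength S and invariance M
    statistics with post-hoc strength-centrality and edge tests). A
    Gaussian-copula synthetic cohort generator with skewed continuous and
    ordinal Likert marginals and planted sparse partial-correlation
    structure supports validation and power studies without access to
    individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
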