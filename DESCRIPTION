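Package: cnnlda
Title: Dual Convolutional Neural Networks with Attention for
    lncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores candidate lncRNA-disease associations from a
    heterogeneous network over lncRNAs, diseases and miRNAs (the CNNLDA
    architecture). Five relation matrices -- lncRNA-disease and
    miRNA-disease associations, lncRNA-miRNA interactions, disease
    semantic similarities and disease-set based lncRNA similarities --
    are assembled into a pairwise feature matrix that is scored by a
    dual convolutional network: a left branch learning a global
    representation and a right branch applying attention at the feature
    and relationship levels. Includes the similarity computation, a
    five-fold cross-validation protocol with per-fold similarity
    recomputation, AUC/AUPR/recall-at-k evaluation, paired Wilcoxon
    comparisons, a seeded generator of synthetic networks with planted
    group structure, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
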