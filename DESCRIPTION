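Package: salcaps
Title: Multilane Capsule Networks for Saliva-Secretory Protein Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts human saliva-secretory proteins from sequence alone with a
    multilane one-dimensional capsule network over normalized position-specific
    scoring matrix (PSSM) encodings. Each lane pairs a 1D convolution of a
    distinct kernel size with a convolutional capsule layer and agreement-based
    dynamic routing; lanes are concatenated and classified through a dense
    softmax head. Class imbalance is handled by a bagging ensemble over balanced
    resamples, thresholds are chosen at maximal Matthews correlation, and
    proteome-wide predictions are ranked by a signed confidence score whose top
    lists are validated against known marker sets with hypergeometric
    statistics. A synthetic motif-implanted sequence generator makes every stage
    testable without external databases or profile searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
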