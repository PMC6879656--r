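Package: lungsig
Title: Mutual-Information Biomarker Discovery for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Yao", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering transcriptomic disease signatures
    that separate two clinically similar conditions (the motivating application is
    chronic obstructive pulmonary disease versus interstitial lung disease).
    Genes are ranked by minimal-redundancy-maximal-relevance (mRMR) scoring of
    discretized expression against the binary disease label, nested top-k gene
    sets are evaluated by incremental feature selection (IFS) with a
    leave-one-out cross-validated support vector machine, and the signature size
    is chosen from the plateau of the IFS curve. Includes cross-platform utilities
    (gene intersection, quantile normalization), a synthetic two-class expression
    generator with planted informative, redundant and noise genes, confusion-matrix
    metrics, and clustering-based reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
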