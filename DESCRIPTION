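Package: modstates
Title: Modular State Detection in Dynamic Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects modular states in dynamic functional connectivity data.
    Given a stack of weighted connectivity matrices (one per sliding time
    window), each window's network is decomposed into modules by an ensemble
    consensus procedure combining seeded Louvain runs with the leading
    eigenvector method, pruned against a permutation null. Pairwise
    partition similarity (normalized z-score of the Rand coefficient) over
    windows yields a window-by-window similarity matrix from which modular
    states are extracted either categorically (consensus clustering of the
    similarity matrix) or consecutively (FDR thresholding, median filtering
    and sequential segmentation along the diagonal). Includes a simulator of
    modular network dynamics with exportable ground truth and validation
    metrics (spatial and temporal similarity, false positive rate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
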