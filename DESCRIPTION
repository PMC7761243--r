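Package: dnea
Title: Differential Network Enrichment Analysis for Metabolomics and Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of two-condition partial-correlation networks
    from metabolomics or lipidomics abundance tables by stability-selected
    nodewise regression with a cross-condition group penalty, consensus
    clustering of the joint network into stable subnetworks, and
    topology-aware enrichment testing of the subnetworks (NetGSA-style
    mixed linear model). Includes feature aggregation for high-dimensional
    lipidomics panels, balanced group subsampling for imbalanced designs,
    group-lasso association of subnetworks with a continuous phenotype,
    and a synthetic two-group data generator with known differential
    network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
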