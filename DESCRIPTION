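Package: connectokit
Title: Graph-Theoretic Analysis of FA-Weighted Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for group-level analysis of structural brain networks
    built from diffusion tractography, where nodes are parcellated brain
    regions and edge weights are mean fractional anisotropy (FA) of the
    connecting white-matter tracts. Computes weighted and binary graph
    metrics (degree, global and local efficiency, betweenness centrality),
    identifies hubs and quantifies hub reorganization via the hub
    disruption index, performs network-based statistics (NBS) with
    permutation family-wise error control, and runs the accompanying
    nonparametric group and clinical-correlation statistics. Includes a
    synthetic cohort generator that plants controlled group differences
    (weakened subnetworks, nodal degree deficits, hub-disruption slopes,
    clinical correlations) so every stage of the pipeline can be validated
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
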