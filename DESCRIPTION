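Package: organtopo
Title: Topological Analysis of Whole-Organ Cellular Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds cell-adjacency networks of whole plant organs from
    labeled 3D segmentations or edge-list exports, and analyses their
    topology at cell-type resolution. Provides interface-area filtering and
    boundary buffering, degree and (weighted, edge, current-flow)
    betweenness centrality with pair-count normalization, distribution
    comparison statistics with Bonferroni control, robustness analysis via
    coefficients of variation, nonparametric mutual information between
    geometric and topological cell features, distribution-distance
    hierarchical clustering, and per-cell tracer concentration
    quantification. A parametric generator of hypocotyl-like cylindrical
    organs (with matching labeled voxel volumes) makes every stage testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    ape,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
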