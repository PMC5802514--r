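Package: scovnet
Title: Structural Covariance Network Analysis for Chronic Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group-level structural covariance network analysis of
    regional brain volumes, as used in cross-species chronic stress research.
    Builds per-group region-by-region correlation networks thresholded across a
    density grid, computes weighted graph metrics (transitivity, clustering,
    modularity, path length, and nodal hubness measures) from first principles,
    and tests group differences by group-label permutation with AUC aggregation
    across densities. Also provides behavioral emotionality z-scoring and PCA,
    per-region volumetric GLMs with FDR control and a-priori-region enrichment,
    focal-node subconnectome comparison, and a latent-factor synthetic cohort
    generator emulating rodent chronic-stress and human childhood-trauma
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
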