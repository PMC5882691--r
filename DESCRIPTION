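Package: vasculonet
Title: Quantitative Analysis of Forming Vascular Networks in Binary Image Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify vasculogenesis from time series of binary
    vessel images: connected-cluster statistics and percolation indicators
    (vessel density, largest-cluster density, cluster counts and area
    distributions), box-counting fractal dimension, skeleton-to-graph
    extraction of the vessel bifurcation network, a planar graph metric
    suite (degree distribution, mean degree, gamma index, average shortest
    path, treeness, clustering, assortativity, largest-component fraction),
    and logistic fits of vessel-density growth. Includes synthetic-data
    generators (logistic density series, diffusion-limited cluster-cluster
    aggregation, planar vascular graphs and rendered image time series)
    emulating control-like tree topologies and anti-angiogenic-treatment-like
    lattice topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
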