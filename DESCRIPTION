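Package: projclust
Title: Clustering Heterogeneous Cryo-EM 2D Projections with Common-Line
    Graphs and Learned Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates 2D projection images of a heterogeneous mixture of
    macromolecular particles into per-particle groups. Builds a common-line
    similarity graph from 1D line projections of the images, embeds graph
    nodes (biased random walks, spectral heat wavelets, or graph infomax),
    learns image embeddings with a triplet-loss Siamese head over a
    convolutional backbone, fuses the representations with a variance-based
    dimensionality reduction rule, and clusters them with density-based and
    graph community methods under semi-supervised model selection. Includes
    a synthetic projection-image generator, a bipartite-matching cluster
    evaluation suite, and an AutoML driver ranking method combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    cluster,
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
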