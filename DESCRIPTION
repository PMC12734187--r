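Package: mdignn
Title: Magnetic Laplacian Graph Neural Networks for Cancer Driver Gene
    Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cancer driver genes from directed gene regulatory
    networks and multi-omics features with a complex-valued graph neural
    network. Edge direction is encoded by the normalized magnetic Laplacian,
    a Hermitian operator whose magnitude carries undirected connectivity and
    whose phase carries directionality. Node features combine per-cancer-type
    mutation, differential methylation and differential expression summaries,
    system-level gene properties, and node2vec topological embeddings, and
    are refined by sequential channel and spatial attention before a fully
    connected scoring head. Includes multi-source network integration with
    confidence filtering, full-batch semi-supervised training with edge
    dropout and early stopping, repeated stratified cross-validation, novel
    candidate ranking, and a synthetic benchmark generator with planted
    driver nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
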