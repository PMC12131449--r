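Package: mxembed
Title: Embedding of Multiplex-Heterogeneous Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Node embedding for universal multilayer networks: several
    multiplex networks over distinct node types (for example genes, drugs
    and diseases) joined by bipartite interaction networks. Node-to-node
    similarity is computed by random walk with restart on the full
    multilayer structure, and embeddings are fitted to that similarity by
    noise-contrastive estimation of a Kullback-Leibler objective. Includes
    a link-prediction evaluation protocol over held-out bipartite edges
    with standard edge operators and a random-forest classifier, spherical
    k-means clustering of the embeddings for module discovery, and a
    planted-partition generator for multiplex-heterogeneous benchmark
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
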