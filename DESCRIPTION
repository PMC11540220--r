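Package: walklink
Title: Biased Random-Walk Embeddings and Link Prediction on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates corpora of biased random walks on undirected graphs
    (uniform, degree-biased, inverse-degree, true self-avoiding, and
    second-order node2vec walks), trains skip-gram negative-sampling node
    embeddings on the walk sequences, scores held-out node pairs by cosine
    similarity for link prediction (AUC-ROC and AUC-PR), and quantifies the
    agreement between walk strategies through Pearson correlation of their
    per-edge similarity profiles and network-topology metrics. Includes a
    synthetic benchmark-graph generator (Erdos-Renyi, Barabasi-Albert,
    Watts-Strogatz, stochastic block model) and an end-to-end reproducible
    pipeline with per-stage artifacts.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
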