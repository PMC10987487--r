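Package: netchrono
Title: Reconstructing the Temporal Order of Edge Arrivals in Grown Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Restores the edge-by-edge growth history of a network from its
    final topology, optionally helped by a few coarse historical snapshots.
    Edges are represented by several node-embedding views plus classical
    link features; an ensemble of antisymmetric pairwise comparators
    predicts which of two edges is younger, and Borda-count aggregation
    turns all pairwise calls into a full arrival sequence. Includes the
    closed-form relationship between pairwise accuracy and sequence error
    with corrupted-ranking simulations to validate it, degree-quantile
    least-squares alignment for transferring a trained comparator ensemble
    to a history-less network, growth-mechanism diagnostics (cumulative
    preferential-attachment kernel, modularity/assortativity/clustering
    trajectories, meso-level labelled adjacency evolution), and
    temporally-weighted truncated-SVD link prediction. Synthetic generators
    (Barabasi-Albert, popularity-similarity optimisation, Bianconi-Barabasi
    fitness) supply networks with full ground-truth arrival order.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
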