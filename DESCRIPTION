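Package: sglrr
Title: Graph-Regularized Low-Rank Representation Clustering with Symmetric and Sparse Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Subspace clustering of sample-by-feature expression matrices via
    low-rank representation with a graph-Laplacian manifold penalty, a symmetry
    constraint and elementwise sparsity (sgLRR). Provides the linearized ADMM
    solver with adaptive penalty (LADMAP), angular-similarity affinity
    construction from the skinny SVD of the representation, normalized-cuts
    spectral clustering, clustering evaluation metrics (accuracy with optimal
    label matching, pairwise Matthews correlation, Rand index, normalized
    mutual information), a union-of-subspaces synthetic data generator, and a
    file-based pipeline with a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
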