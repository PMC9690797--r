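Package: ubrw
Title: Bipartite Link Prediction by Similarity Fusion and Unbalanced
    Bi-Random Walk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts links in a sparse bipartite lncRNA-disease
    association network. Disease similarity is computed from MeSH-style
    term hierarchies (directed acyclic graphs with hop-decayed term
    contributions), lncRNA functional similarity from associated disease
    sets, and both are fused with logistic-rescaled Gaussian interaction
    profile kernels. The fused similarities drive weighted K-nearest
    known-neighbor (WKNKN) preprocessing of the association matrix,
    linear neighborhood similarity weights obtained by simplex-constrained
    quadratic programming, and an unbalanced bi-random walk with restart
    over the two entity networks. Includes leave-one-out and repeated
    k-fold cross-validation with AUC scoring, top-k candidate reports,
    and a seeded synthetic data generator (term hierarchy plus
    planted-block association matrix) for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
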