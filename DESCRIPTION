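Package: scVDMC
Title: Variance-Driven Multitask Clustering of Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint clustering of several single-cell RNA-seq populations
    (biological replicates, donors, or patient samples) that share cell types
    and marker genes but differ in expression scale and technical bias. The
    model is a k-means-style matrix factorization with an embedded
    cardinality-constrained marker-gene selection, a within-domain
    cluster-center separation term, and a cross-domain center agreement
    penalty, solved by alternating minimization. Includes hyperparameter
    utilities (a Gershgorin positive-semidefiniteness bound on the separation
    weight, an elbow statistic for the number of clusters, a center-agreement
    diagnostic for the coupling weight), pooled and separated k-means
    baselines with variance-based gene selection, clustering evaluation
    metrics, standard preprocessing filters, a multi-domain synthetic data
    generator with planted markers, and readers/writers for dense TSV and
    MatrixMarket expression matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
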