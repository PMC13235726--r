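Package: scjudge
Title: Visual Tournament Selection of Single-Cell Preprocessing Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatically selects a preprocessing pipeline for single-cell
    and single-cell-resolution spatial transcriptomics count data. A grid of
    candidate pipelines (normalization, highly-variable-feature selection,
    number of principal components, clustering resolution) is executed, each
    result is rendered as a standardized two-dimensional embedding image, and
    a winner is chosen through a sequential pairwise tournament driven by a
    pluggable visual judge: a vision language model over a thin transport
    contract, or deterministic and noisy metric oracles for offline use and
    benchmarking. Also includes a read-downsampling simulator that emulates
    imaging-based spatial data (reduced gene panel, lower depth) from
    annotated scRNA-seq references, a clustered negative-binomial synthetic
    data generator, and a five-metric clustering evaluation suite (ARI,
    Silhouette, Calinski-Harabasz, 1-Davies-Bouldin, Mutual Information)
    with the benchmark protocols for judge accuracy and selection quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    uwot,
    RANN,
    png,
    mclust,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
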