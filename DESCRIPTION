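Package: vizclust
Title: Transformation- and Method-Dependence of Visual Clustering for Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how expression-value transformations
    (unprocessed FPKM, log10 with the exact-zero rule, log10 + 1) interact
    with nonlinear dimension-reduction methods when bulk transcriptomes are
    clustered visually. Provides a t-SNE stage with fixed preprocessing, a
    from-scratch adapted UMAP (smooth k-nearest-neighbour bandwidth
    calibration, half-sum symmetrisation, normalised-Q cross-entropy
    gradient descent), k-means and Leiden clustering of embeddings, a
    scale-dependent k-nearest-neighbour overlap measure of map similarity,
    UTMC (unit/transformation/method/clustering) figure legends, a grid
    runner that quantifies cluster-label associations, and a synthetic
    FPKM generator with planted subgroups, exact zeros, expression-independent
    site labels and an optional primary-metastatic gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
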