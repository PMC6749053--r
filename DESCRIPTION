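Package: cellslc
Title: Label-Free Cell-Type Classification and Self-Label Clustering of
    Brightfield Single-Cell Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies cell types from label-free brightfield single-cell
    crops with a six-block convolutional network, and discovers morphological
    phenotypes within a cell type by Self-Label Clustering (SLC): each cell's
    augmented copies form their own class, a network is trained on these
    self-classes, and the pooled last-convolutional activations (LCA) are
    k-means clustered with silhouette model selection.  Includes a synthetic
    single-cell image generator with ground-truth phenotype modes, density
    conditions and flask-level batch effects, quantile-normalization and
    augmentation preprocessing, cluster-enrichment analysis across conditions,
    minimal morphometrics (area, skeleton endpoints, co-occurrence sum
    variance) and Jensen-Shannon feature ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
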