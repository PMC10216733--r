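Package: dshcca
Title: Deep Subspace Reconstruction and Hypergraph-Regularized Temporal
    Sparse Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Longitudinal phenotype-genotype association via temporally
    constrained group-sparse canonical correlation analysis (TGSCCA) with
    hypergraph-Laplacian smoothness penalties on projected sample scores,
    optionally preceded by a label-guided deep subspace reconstruction of
    each data view (DS-HBTGSCCA). Includes a coupled latent-factor
    simulator for one static gene-expression view and several drifting
    longitudinal phenotype views, KNN hypergraph construction with the
    normalized hypergraph Laplacian, evaluation metrics (canonical
    correlation, R-squared, support recovery, clustering indices), and
    experiment drivers for noise sweeps, hyperparameter grid search,
    regression checks and reconstruction-versus-raw clustering
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
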