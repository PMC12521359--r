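Package: schicbench
Title: Multiscale Embedding and Benchmarking of Single-Cell Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A decoupled toolkit for single-cell Hi-C (scHi-C) embedding and
    clustering benchmarks. Reads per-cell cis contact lists, applies
    exchangeable preprocessing transforms (VC-sqrt normalization, box-filter
    smoothing, random-walk imputation with restart, inverse-document-frequency
    weighting, distance truncation, stratum z-scoring), and embeds cells with
    seven backends: 1D bin-coverage PCA, scHiCluster-style per-chromosome PCA,
    stratum inner-product and stratum-adjusted-correlation similarity with
    classical MDS, IDF-weighted spectral embedding, latent Dirichlet
    allocation over locus pairs, insulation-score delta vectors, and a
    convolutional variational autoencoder with a Gaussian-mixture latent
    prior. Includes the ARI/NMI/ASW/AvgBIO evaluation stack with repeat
    harness and median-rank summaries, per-stratum similarity diagnostics,
    pseudo-bulk A/B compartment calling, and a multiscale synthetic scHi-C
    generator with known labels for controlled experiments on
    compartment-scale versus loop-scale heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
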