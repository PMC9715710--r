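Package: uotvae
Title: Unpaired Single-Cell Multi-Omics Integration with a Coupled VAE and
    Unbalanced Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates unpaired single-cell datasets measured in different
    modalities (scRNA-seq, scATAC-seq gene-activity scores, spatial
    transcriptomics) into a shared latent space. A coupled variational
    autoencoder with one dataset-free probabilistic encoder, a common decoder
    with dataset-specific batch normalization and per-dataset specific-gene
    decoders is trained jointly with a minibatch unbalanced optimal-transport
    alignment loss on the latent Gaussians. The fitted model supports
    cross-modality gene imputation, transport-plan label transfer and spatial
    spot deconvolution, and ships the standard integration-quality metric
    suite (kNN-transfer ARI/NMI/F1, scaled silhouette, batch entropy,
    FOSCTTM) plus a synthetic two-modality data generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    cluster
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
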