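Package: scMosaicVAE
Title: Multimodal and Mosaic Integration of Single-Cell Data with an
    Adversarial Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous horizontal (batch) and vertical (cross-modality)
    integration of paired single-cell multimodal data (RNA+ATAC, RNA+ADT) and
    mosaic integration of paired with unimodal data. Implements a variational
    autoencoder with a logistic-normal latent space, modality-specific
    negative-binomial and negative-multinomial likelihoods, batch-conditioned
    decoding, and a tunable batch-adversarial training strategy based on
    gradient reversal. Includes a synthetic multimodal data generator with
    known ground truth, integration metrics (iLISI, NMI, average silhouette
    width), and a command-line interface wiring simulation, training,
    embedding and evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    cluster,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
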