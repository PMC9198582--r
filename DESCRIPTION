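Package: berryvae
Title: Unsupervised Detection of Damaged Grapevine Berries with a
    Feature-Perceptual Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patch-based pipeline for finding damaged or diseased grapevine
    berries in field images without any labels for damage. A variational
    autoencoder is trained with a feature perceptual loss on image patches of
    healthy berries only; at inference time, patches whose reconstruction error
    exceeds an optimised threshold are flagged as anomalous, and pixel-wise
    reconstruction-error heatmaps localise the damaged regions within full
    images. Includes baseline convolutional autoencoders trained with SSIM and
    feature perceptual losses, a synthetic berry-scene generator with ground
    truth masks for fully self-contained evaluation, region-of-interest patch
    extraction from segmentation masks, threshold optimisation and growth-stage
    stratified accuracy reporting, and an end-to-end reproducible command-line
    pipeline. The neural-network core (convolutions, batch normalisation,
    backpropagation, Adam) is implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    grDevices,
    tools,
    utils,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
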