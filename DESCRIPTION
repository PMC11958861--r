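Package: dvrnet
Title: MRI-to-Synaptic-Density PET Translation with a 3D Convolutional
    Encoder-Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired structural (T1-weighted MRI analog) and synaptic
    density ([11C]UCB-J BPND analog) brain volumes, computes distribution
    volume ratio (DVR) parametric targets against a cerebellum-analog
    reference region, trains a symmetric 3D convolutional encoder-decoder
    with valid padding on random 3D patches, performs tiled whole-volume
    inference, and evaluates predictions with global and region-of-interest
    image-quality metrics (MSE, global-moment SSIM, percentage bias,
    Pearson correlation) under stratified k-fold cross-validation with
    low-dose-always-test handling and leave-one-disease-out designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
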