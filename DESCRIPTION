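Package: usgan
Title: Unsupervised Ultrasound B-Mode Image Enhancement with a Switchable CycleGAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unpaired grey-scale B-mode ultrasound image-quality translation
    between a low-quality and a high-quality device domain using a switchable
    cycle-consistent adversarial network: a single shared convolutional
    generator whose translation direction is selected by adaptive instance
    normalization (AdaIN) codes emitted by a small code-generator network,
    trained against two patch-level discriminators with cycle-consistency and
    identity losses. Includes a seeded synthetic speckle phantom generator
    producing the two unpaired quality domains with ground-truth regions of
    interest, classical shock- and bilateral-filter enhancement baselines,
    and a quantitative evaluation suite (contrast ratio, contrast-to-noise
    ratio, patch-wise SSIM, first-order statistics, grey-level co-occurrence
    matrix texture features, and a Frechet distance on pluggable image
    features). All networks run on the CPU via compiled im2col/GEMM
    convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    e1071,
    pracma
Config/testthat/edition: 3
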