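Package: texfuse
Title: Texture-Depth Feature Fusion Networks for Grayscale Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hand-crafted texture features (six local binary pattern variants
    and a configurable histogram of oriented gradients) rendered as grayscale
    feature images and fused, by element-wise Add with learnable per-channel
    kernels, into a modified VGG-16 style convolutional classifier (C-VGG /
    FC-VGG) at a configurable depth. Includes stratified k-fold training and
    evaluation with accuracy, precision, recall and F1 under weighted or macro
    averaging, a synthetic two-class radiograph-like image generator whose
    class signal is carried by local texture, and parameter-sweep harnesses
    for the LBP variant, HOG cell size and fusion position.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
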