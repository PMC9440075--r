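Package: sgtnet
Title: Scaled-Gamma-Tanh Activation Layers for 3D Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the scaled-gamma-tanh (SGT) activation function: a
    two-step nonlinearity that applies a learnable per-channel power-law
    ("gamma") transform followed by a hyperbolic-tangent squash, together
    with its custom backward-propagation rules. Around the activation the
    package provides a compact, fully testable 3D convolutional
    classification stack for volumetric greyscale images (diverging-kernel
    architecture, batch normalization, max pooling, fully connected head),
    an Adam/SGDM training loop with a stepped learning-rate schedule,
    stratified data splitting, confusion-matrix metrics (accuracy, Cohen's
    kappa, class-wise precision), a synthetic labelled-volume generator
    emulating greyscale MRI, NIfTI input/output, and diagnostic reports
    (activation curves, layer histograms, learnable-exponent summaries,
    fully-connected weight correlations, feature export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    graphics,
    jsonlite,
    RNifti,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
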