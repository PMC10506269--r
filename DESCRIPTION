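Package: cacnet
Title: Concatenated Attention-Augmented Convolutional Networks for DNA
    Sequence Classification
Version: 0.1.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org",
           role = c("aut", "cre"))
Description: Multi-label classification of DNA sequences (for example
    transcription-factor occupancy of ChIP-seq derived windows) with a
    network whose feature layers concatenate parallel attention-augmented
    convolution branches: each branch joins ordinary 1D convolution
    channels with multi-head scaled dot-product self-attention channels.
    Implements the full model in base R (forward pass, exact analytic
    gradients, SGD with momentum, early stopping on validation accuracy),
    one-hot sequence encoding and FASTA input, a seeded position-weight-
    matrix motif simulator for generating labelled benchmark datasets, and
    multi-label evaluation (top-k accuracy, per-class ROC/AUC and average
    precision) with a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
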