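Package: ncsdx
Title: Automated Carpal Tunnel Syndrome Diagnosis from Nerve Conduction Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two complementary machine-learning pipelines for automated
    diagnosis of carpal tunnel syndrome (CTS) from nerve conduction study
    (NCS) recordings. Motor compound muscle action potentials (CMAP) are
    turned into Hann-window short-time Fourier transform spectrogram images
    and classified (control vs. patient) by a compact three-block 2-D
    convolutional network implemented from scratch with Rcpp/Armadillo.
    Sensory nerve action potentials (SNAP) from the median and ulnar nerves
    are decomposed with a Haar multilevel wavelet pyramid, summarised into a
    135-element per-hand feature vector (12 statistical and 3 non-statistical
    features per sub-band) and graded into three severity classes by a bank
    of classical classifiers with grid-search cross-validation. A parametric
    SNAP/CMAP waveform simulator with severity effects and Gaussian-noise
    duplication augmentation makes the whole system buildable and testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
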