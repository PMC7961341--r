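Package: bivdann
Title: Subject-Generalized EEG Emotion Recognition with Bilateral
    Variational Domain-Adversarial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for subject-independent emotion recognition from
    multichannel EEG. Recordings are cut into overlapping windows,
    converted to three-band (alpha, beta, gamma) 64x64 spectral
    topographs via multitaper power estimation and scalp interpolation,
    and split into hemispheric images. A bilateral model couples two
    hemispheric beta variational autoencoders with a bilateral
    convolutional feature extractor, an emotion classifier and a
    gradient-reversal subject discriminator, trained by an interleaved
    schedule so that the shared embedding separates emotion classes
    while becoming invariant to subject identity. Includes a synthetic
    multi-subject generator with controllable class and subject effect
    sizes, leave-one-subject-out evaluation, linear subject probes and
    latent-normality diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    nnet
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
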