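Package: tcvaegan
Title: Transformer Conditional VAE-GAN for EEG Signal Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-conditioned generation of multichannel EEG segments with a
    transformer-based conditional variational autoencoder trained adversarially
    against a 1-D convolutional discriminator. The generator is optimized with a
    six-term dynamically weighted objective (reconstruction, KL, adversarial,
    Pearson correlation, temporal smoothness, Welch power-spectrum consistency)
    whose per-batch weights are obtained by z-scoring, softmax, clipping to
    [0.1, 0.4] and renormalization. Includes a synthetic multichannel EEG cohort
    generator with 1/f background and class-dependent band-power structure, EDF
    and sliding-window preprocessing utilities, a spectral evaluation suite
    (paired Pearson/Spearman, spectral KL divergence, feature-space Frechet
    distance, PSD-MSE, spectral earth mover's distance), and frozen-classifier
    congruence and augmentation protocols for downstream emotion classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    signal,
    pracma,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
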