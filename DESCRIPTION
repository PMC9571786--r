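Package: ramangrade
Title: Two-Stage Deep Cascade for Grading Chondrogenic Tumors from Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies Raman spectra of bone and cartilage tissue into
    enchondroma (E), grade-1 chondrosarcoma (G1) and high-grade
    chondrosarcoma (G2G3) with a two-stage cascade: a small 1D
    convolutional network separates EG1 from G2G3 on z-scored spectra,
    then a residual 2D convolutional network, applied to synchrosqueezed
    continuous-wavelet-transform scalograms rendered as JET RGB images,
    separates E from G1. Includes a generalized Morse wavelet transform
    with synchrosqueezing and inversion, shallow baselines (PCA+SVM,
    PCA+LDA, LDA, multilayer perceptron), per-class and aggregated
    cascade accuracy reports, class-activation-map explainability mapped
    back to wavenumber intervals, and a seeded synthetic Raman cohort
    simulator with grade-dependent collagen, chondroitin-sulfate,
    hydroxyapatite and nucleic-acid band structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    MASS,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
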