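Package: pwdtrace
Title: Velocity-Envelope Tracing and Cardiac-Cycle Classification for Fetal Pulsed-Wave Doppler
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolbox for tracing upper and lower maximum-velocity
    envelopes from pulsed-wave Doppler (PWD) spectrogram strips of the fetal
    heart. Twenty-three interchangeable processing options are organised into a
    six-slot workflow (image smoothing, contrast enhancement, binarisation,
    mask clean-up, envelope extraction, envelope smoothing), together with a
    windowed 264-feature neural classifier that flags complete and measurable
    fetal cardiac cycles, chain-assessment machinery (single-substitution
    enumeration, greedy near-optimal search, literature-chain comparison,
    leave-one-subject-out evaluation with nonparametric statistics), and a
    synthetic PWD-strip generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    nortest,
    igraph,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
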