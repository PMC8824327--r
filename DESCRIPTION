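Package: eaemd
Title: Calibration-Time Reduction for Motor-Imagery BCIs by Aligned
    Empirical-Mode Data Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments small motor-imagery EEG training sets by decomposing
    Euclidean-aligned trials into intrinsic mode functions (EMD) and
    recombining them at random, within class, into artificial trials.
    Includes the full evaluation pipeline: Butterworth band-pass
    preprocessing, epoching, central-channel selection, Euclidean
    alignment, common spatial pattern (CSP) feature extraction,
    closed-form linear discriminant analysis and Newton-fitted logistic
    regression classifiers, learning-curve evaluation with paired t-tests,
    and a seeded generator of two-class motor-imagery-like EEG with known
    ground truth for end-to-end testing without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    broom,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
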