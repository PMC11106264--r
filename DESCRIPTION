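Package: actisleep
Title: Sleep Staging and Sleep Architecture from Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to infer sleep stages and sleep-architecture parameters
    from raw wrist-worn tri-axial accelerometry. Includes signal
    preprocessing (resampling, clipping, epoching, non-wear detection,
    quality control), a self-supervised deep recurrent sleep stager built
    from a 1D-convolutional residual feature extractor and a bidirectional
    LSTM, random-forest time-in-bed detection with hidden Markov model
    smoothing, derivation of per-night sleep parameters (total sleep
    duration, sleep efficiency, WASO, REM/NREM durations and ratios),
    an agreement-evaluation battery (Cohen's kappa, macro F1, balanced
    accuracy, Bland-Altman limits of agreement), wear-time missing-data
    simulation via intraclass correlation, and a synthetic multi-night
    cohort generator with ground-truth hypnograms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
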