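Package: earsleep
Title: Automated Sleep-Wake Staging from Around-the-Ear EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic sleep staging of
    around-the-ear EEG (cEEGrid-style electrode arrays): preprocessing
    (resampling, band-pass and notch filtering, envelope-based alignment,
    power-threshold artifact rejection), correlation-index ranking of
    pooled electrode derivations against scalp references, extraction of
    33 spectral, temporal and sleep-event features per 30-s epoch, a
    bagged decision-tree stager with leave-one-subject-out validation,
    rule-based hypnogram post-processing (persistent-sleep onset, final
    wake-up, probability smoothing with wake retention), an actigraphy
    sleep-wake scorer, and agreement statistics (Cohen's kappa, ICC(A,1),
    paired tests, sleep statistics). Includes a synthetic sleep-EEG
    generator with stage-dependent spectra, spindles, slow waves, eye
    movements, movement artifacts and correlated actigraphy counts, so
    the whole pipeline can be exercised without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
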