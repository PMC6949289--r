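Package: iemgkit
Title: Acquisition-Side Processing for Multi-Channel Intramuscular EMG Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for working with multi-channel intramuscular
    electromyography (iEMG) recordings acquired alongside isometric hand-force
    measurements: reading and writing the session and spike-sort MAT-file
    container layouts, powerline-harmonic notch filtering with zero-phase
    application, dual-device synchronization-pulse detection and alignment,
    force calibration and up-sampling, three-pass template-matching motor-unit
    spike sorting, RMS envelope extraction, movement-code protocol semantics,
    and quantitative quality control (channel cross-correlation, spectral
    percentile summaries, channel/force pairing).  Includes a ground-truth
    annotated synthetic session generator emulating the recording protocol,
    motor-unit physiology and interference structure, so every processing
    stage can be exercised and validated without access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
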