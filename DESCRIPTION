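Package: eventconn
Title: Event-Coupling Functional Connectivity for Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for interictal intracranial EEG functional
    connectivity based on band-limited oscillatory events. Detects local
    amplitude maxima in theta, low-gamma and high-gamma filtered signals,
    builds peri-event lag histograms for every channel pair, and converts
    histogram Shannon entropy into a normalized connectivity index in [0,1].
    Includes preprocessing (rational resampling to 1 kHz, 60 Hz notch,
    zero-phase FIR band-pass), a spectrum-whitening interictal spike detector
    and spike-coupling rate matrices, inter-contact Euclidean distances with
    exponential distance-decay fitting, seizure-onset-zone and region network
    labeling of channel pairs, a mixed-effects group-statistics stage, and a
    seeded synthetic-data generator that emulates coupled oscillatory event
    trains with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
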