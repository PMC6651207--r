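Package: eegkata
Title: Cross-Correlation Connectivity and a Convolutional Soft Sensor for
    Problem-Solving EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of 14-channel EEG recorded while
    subjects execute two lean-management problem-solving routines (KATA and
    (CPD)nA). Provides a latent-source synthetic EEG generator with a
    closed-form correlation oracle, causal Butterworth preprocessing with
    range normalization and 1-s segmentation, zero-lag cross-correlation
    connectivity analysis of prefrontal and temporoparietal sensor pairs
    with four region-coupling hypotheses, an RGB multichannel image encoder,
    and a convolutional soft sensor (trained from scratch, no external
    deep-learning runtime) that discriminates the two behavioral patterns
    from encoded 1-s segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
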