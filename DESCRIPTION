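Package: eegstates
Title: Spectral Indices and Multi-Index Decision Analysis for EEG Cognitive States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed power-spectral analysis of multi-channel EEG for
    discriminating cognitive states such as meditation versus engaged
    task conditions. Computes per-window spectral Shannon entropy (H),
    Pearson's first skewness coefficient of the spectral distribution
    (PSk), total power (TP) and dominant-frequency indices (DF, DFs),
    maps 128-channel recordings onto a 12x12 scalp grid, aggregates
    indices hierarchically (window, electrode, participant, group) with
    t-based confidence intervals, and combines pairwise unequal-variance
    t-tests across the four indices into an Accept/Neutral/Reject
    decision matrix between experimental modalities. Includes a seeded
    synthetic multi-channel EEG generator (band-limited random-phase
    oscillations over a 1/f background) that emulates alpha-dominant and
    broadband states for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    nortest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
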