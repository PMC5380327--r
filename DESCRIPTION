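Package: smfstools
Title: Simulation and Analysis of Single-Molecule Force Spectroscopy
    Pulling Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for atomic force microscopy (AFM) single-molecule force
    spectroscopy on tandem polyproteins: worm-like-chain (WLC) fitting of
    unfolding peaks, Bell-Evans dynamic force spectroscopy (loading-rate
    analysis of unfolding forces), contour-length accounting, thermal-tune
    cantilever calibration from thermal-noise power spectra, per-curve force
    statistics, and a Monte Carlo simulator of constant-speed pulling
    experiments on multi-domain constructs that produces sawtooth
    force-extension curves with ground-truth event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
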