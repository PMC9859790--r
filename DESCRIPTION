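Package: oddballerp
Title: Simulation and Analysis of P300 Oddball Experiments on Four-Channel Mobile EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for visual-oddball event-related potential (ERP)
    studies recorded on four-channel consumer EEG headbands (TP9, AF7, AF8, TP10
    referenced to FPz). Generates constrained oddball trial sequences, simulates
    continuous EEG with 1/f background noise, blink artifacts, Gaussian N200/P300
    templates and Bluetooth marker lag, preprocesses recordings (zero-phase
    Butterworth band-pass and notch filtering, virtual-electrode pooling,
    epoching, baseline correction, peak-to-peak artifact rejection, participant
    exclusion), quantifies N200/P300 peaks on conditional, difference and grand
    average waveforms, and analyses 2 x 2 fully repeated-measures designs
    (within-subject ANOVA, paired-t interaction decomposition, partial eta
    squared, Cohen's d, Cousineau-Morey within-subject confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
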