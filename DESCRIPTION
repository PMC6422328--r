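Package: affectbci
Title: Closed-Loop Music-Based Affective Brain-Computer Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a closed-loop, music-based
    affective brain-computer interface. Provides a rule-based affective music
    synthesis engine driven by continuous valence/arousal parameters (church-mode
    harmony, tempo, rhythmic density, register and loudness mappings, Standard
    MIDI File output), an EEG band-power + linear discriminant affect decoder
    with the full calibration pipeline (segmentation, zero-phase Chebyshev
    band-pass filtering, log-variance features, idle baseline, standardization,
    regularized LDA, sigmoid scoring), the calibration and rest/action trial
    protocols that close the loop between decoder scores and music parameters,
    an evaluation battery (repeated cross-validation with binomial chance
    threshold, modulation statistics with one-tailed paired t-tests, band-power
    contrasts, mood correlations, pairwise Granger causality), and a synthetic
    EEG generator with a simulated responder so the entire system is exercisable
    end-to-end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
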