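Package: ffrpipe
Title: Frequency-Following Response Analysis Pipeline
Version: 0.1.0
Authors@R: person("FFR", "Pipeline Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible analysis pipeline for speech-evoked
    frequency-following responses (FFR). Simulates cohort-scale multi-sweep
    EEG recordings to a harmonic speech-like stimulus, preprocesses sweeps
    (Butterworth bandpass filtering, artifact rejection, baseline correction,
    polarity-subtracted averaging), extracts stimulus-anchored spectral
    features (fundamental, harmonics, formant-band means) from region-wise
    FFTs, and runs split-plot mixed ANOVAs with Fisher LSD post-hoc tests and
    Cohen's d effect sizes. Includes a command-line workflow with text-based
    file formats, run manifests and summary figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
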