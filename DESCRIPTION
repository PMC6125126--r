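Package: fearlfp
Title: Dual-Region LFP Analysis for Auditory Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel local field potential (LFP)
    recordings from the dorsomedial prefrontal cortex (dmPFC) and basolateral
    amygdala (BLA) during auditory fear conditioning and extinction: pip-aligned
    auditory evoked potential (AEP) averaging and first-peak/first-trough
    amplitude scoring, complex Morlet wavelet time-frequency maps with
    per-frequency z-scoring and pre-stimulus baseline subtraction, evoked
    theta-band (2-12 Hz) power, Welch magnitude-squared coherence, amplitude
    envelope cross-correlation lead/lag estimation with a circular-shift
    surrogate significance test, freezing-behavior quantification over
    two-trial blocks, and the accompanying repeated-measures group statistics.
    Includes a synthetic dual-region LFP generator with known ground truth
    (shared band-limited theta source with configurable coupling and
    directional delay, evoked response templates, pink background noise) so
    that every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
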