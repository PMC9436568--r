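Package: sssepbci
Title: Simulation and Classification of High-Frequency SSSEP Selective-Attention EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for steady-state somatosensory evoked potential (SSSEP)
    brain-computer interface analysis: simulation of vibrotactile
    selective-attention EEG sessions with planted steady-state oscillations,
    contralateral scalp topography and 1/f background noise; screening for
    subject-specific resonance-like stimulation frequencies from attention
    versus inattention amplitude spectra; common spatial pattern (CSP) and
    filter-bank CSP (FBCSP) feature extraction; mutual-information-based
    best individual feature (MIBIF) selection; kernel support-vector
    classification under a stratified bootstrap protocol; and the
    accompanying statistical apparatus (adjusted chance level, repeated
    measures method comparison, a-priori power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
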