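Package: meterlab
Title: Stimulus Construction and Frequency-Tagging Analysis for Rhythm and
    Meter Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-tagging studies of rhythm and meter
    processing. Enumerates cyclic rhythmic patterns (binary necklaces),
    scores their syncopation against nested metric templates, and builds
    seeded sequences that morph between metrically regular and degraded
    rhythms together with their time-inverted twins. Provides a gammatone
    ERB filterbank with hair-cell transduction as a model of the auditory
    periphery, a shared spectral engine (overlapping segmentation, trial
    averaging, FFT magnitude spectra, neighbouring-bin noise subtraction,
    target-frequency extraction and z-scoring of meter-frequency
    prominence), an EEG analysis pipeline, finger-tapping synchronization
    measures, and synthetic EEG/tapping generators with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
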