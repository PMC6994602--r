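Package: ecogface
Title: Spatiotemporal Analysis of Face-Selective Responses in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for analysing category-selective responses in
    intracranial (ECoG) recordings: raw-signal preprocessing (notch filtering,
    resampling, channel quality control, common-average referencing, epoching,
    Morlet-wavelet high-frequency broadband power), permutation-based
    classification of recording sites into active, face-selective and human
    face-selective classes with FDR control, kernel SVM decoding of faces
    versus non-faces over configurable site sets including a sparse
    multiple-kernel-learning variant, trial-level response onset latency
    estimation with posterior-anterior gradient analysis, and two-proportion
    tests for electrical-stimulation outcomes. A synthetic ECoG generator with
    planted category-selective effects, and a ramp-injection signal-to-noise
    semi-simulation, make every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    kernlab,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
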