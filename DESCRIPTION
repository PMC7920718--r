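Package: nirsbci
Title: Decoding Walking Imagery from fNIRS Signals with Class-Dependent
    Sparse Representation
Version: 0.1.0
Authors@R: person("nirsbci", "maintainers", email = "nirsbci@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding walking imagery versus idle state from
    functional near-infrared spectroscopy (fNIRS) recordings. Includes a
    synthetic dual-wavelength fNIRS generator with a known hemodynamic
    ground truth, Modified Beer-Lambert law conversion between optical
    density and hemoglobin concentration changes, preprocessing
    (first-order Butterworth band-pass, correlation-based signal
    improvement for motion artifacts, baseline drift correction),
    per-trial mean/peak/RMS feature extraction, a class-dependent sparse
    representation classifier built from per-class orthogonal matching
    pursuit residuals fused with class-dependent K-nearest-neighbor
    distances, four reference classifiers (RBF SVM, KNN, LDA, logistic
    regression), and per-subject leave-one-out cross-validation with
    Friedman and Wilcoxon signed-rank comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
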