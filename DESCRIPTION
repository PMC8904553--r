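Package: fpscreen
Title: Fabry-Perot Interferogram Simulation and Machine-Learning Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates low-coherence Fabry-Perot interferometer spectra for
    refractive-index liquid panels, maps each interferogram to an 18-feature
    row (fringe maxima statistics, amplitude normalisation, Simpson-rule
    distortion, axial shift, RMSE against the theoretical two-beam signal),
    labels rows by refractive index as healthy or neoplastic tissue analogs,
    and trains and evaluates random-forest, gradient-boosted-tree, Gaussian
    naive-Bayes and dense neural-network classifiers under stratified k-fold
    cross-validation with a held-out validation split.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    xgboost,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
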