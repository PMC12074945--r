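Package: fittnet
Title: Individualized FITT Exercise-Prescription Networks Trained by
    Levenberg-Marquardt
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds individualized cardiorespiratory-fitness exercise
    prescriptions (frequency, intensity, time, volume) for older adults from
    a small multilayer perceptron trained from scratch with a damped
    Gauss-Newton (Levenberg-Marquardt) optimizer with L2 regularization and
    early stopping. Includes deterministic encoding of subject profiles and
    prescriptions, Gaussian augmentation of study-level summary statistics
    into subject-level training corpora, nested cross-validation with grid
    search, and validation statistics: error ratios with tolerance bands,
    improvement hit rates, Bland-Altman limits of agreement, and
    expected-versus-observed regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
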