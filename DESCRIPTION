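Package: holospec
Title: Holo-Hilbert Spectral Analysis of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-layer empirical mode decomposition (improved CEEMDAN) of
    multichannel resting-state EEG into joint amplitude-modulation by
    carrier-frequency (Holo-Hilbert) spectra on a dyadic band grid, with
    cluster-based nonparametric permutation contrasts between groups,
    signature/ratio feature construction with correlation pruning and
    boosting-based feature selection, and a seven-classifier cross-validated
    evaluation panel. Includes a synthetic EEG cohort generator with
    controllable amplitude-modulation structure, 1/f aperiodic background and
    planted group effects, plus EDF input/output, so the full pipeline is
    testable end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    rpart,
    class,
    pROC,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
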