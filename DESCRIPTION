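Package: tfdp
Title: Tear-Fluid Denaturation Profiling by Simulated nanoDSF and
    Thermogram Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of nanoDSF (label-free differential
    scanning fluorimetry) melting scans of tear-fluid protein mixtures. A
    mechanistic two-state (van't Hoff) forward model generates 330/350 nm
    fluorescence scans for single proteins and mixtures of the five core
    tear proteins, including ligand-induced melting-temperature shifts
    (myristic acid, ferric iron). A phenomenological generator produces
    labelled two-class patient-like cohorts. The analysis pipeline builds
    the six-curve denaturation profile (F330, F350, their ratio and first
    derivatives), extracts the two-peak (T1m, T2m) biomarker from the
    derivative of the fluorescence ratio, clusters subjects by
    two-parameter k-means, and benchmarks four machine-learning
    classifiers (logistic regression, polynomial SVM, random forest,
    AdaBoost) under stratified 5-fold cross-validation with leakage-safe
    scaling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    rpart,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
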