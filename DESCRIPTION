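Package: vfforecast
Title: Early Prediction of Ventricular Fibrillation from HRV and QRS Shape Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict the onset of ventricular fibrillation (VF) from a
    120-second electrocardiogram window ending 30 seconds before onset. Extracts
    eleven heart-rate-variability features (time domain, Welch band powers,
    Poincare dispersions) and four QRS-complex shape features (signed area and
    R-peak amplitude statistics), classifies VF-prone versus control segments
    with a small feed-forward neural network and four comparison classifiers,
    and evaluates with repeated stratified 10-fold cross-validation, ROC/AUC and
    group statistics. A synthetic ECG/RR generator with full ground truth makes
    the whole pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    e1071,
    class,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
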