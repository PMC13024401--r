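Package: ecgrhythm
Title: Single-Lead ECG Rhythm Classification with a Time2Vec Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 10-second single-lead electrocardiogram (ECG) strips
    into five rhythm categories (normal sinus rhythm, sinus tachycardia,
    sinus bradycardia, supraventricular tachycardia, ventricular
    tachycardia). Each strip is resampled to 250 Hz, z-score normalized,
    decomposed into 1-second sliding windows with a 5-point stride, and each
    window is scored by a lightweight transformer encoder whose positional
    information comes from a learnable Time2Vec embedding; per-window
    predictions are fused by majority voting. Includes a seed-controlled
    synthetic five-rhythm ECG generator with patient-wise train/validation/
    test partitioning, WFDB and CSV readers and writers, a from-scratch
    training loop, and a per-class evaluation battery (accuracy,
    sensitivity, specificity, precision, F1, one-vs-rest ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
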