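Package: ictalwear
Title: Multimodal Wearable Seizure Detection from Wrist-Worn Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of focal onset motor seizures from wrist-wearable
    biosignals (3-axis accelerometry, electrodermal activity, blood volume
    pulse). Provides readers and writers for per-channel CSV session
    recordings, recurrence-quantification features on accelerometry,
    baseline-differenced skin-conductance features, photoplethysmography beat
    detection with filtered heart-rate estimation and a spectral-entropy
    signal-quality index, a cost-weighted AdaBoost tree-ensemble detector with
    grid-search hyperparameter optimization, event-based scoring (sensitivity,
    false alarm rate per 24 h and per night, positive predictive value), and
    leave-one-seizure-out / leave-one-participant-out evaluation harnesses. A
    synthetic multimodal cohort generator emulates ictal movement bursts,
    electrodermal responses, tachycardia and motion artifact so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rpart,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
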