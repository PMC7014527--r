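Package: chewdet
Title: Chewing-Cycle Based Eating-Event Detection from Wearable EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects eating events in multi-channel surface electromyography
    (EMG) from chewing-monitoring wearables. Implements a bottom-up pipeline
    that first detects individual chewing-cycle onsets with a windowed
    conditional-count statistic and then infers eating events from chewing
    density, plus two top-down baselines (an EMG-work threshold detector and a
    windowed one-class SVM). Includes time-overlap retrieval metrics
    (precision, recall, F1) and start/end timing-error metrics for event-based
    evaluation, grid search with leave-one-participant-out cross-validation,
    and a synthetic two-channel temporalis-EMG generator with chew-accurate
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
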