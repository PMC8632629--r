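Package: szgraph
Title: Similarity-Graph Deep Learning for Seizure Prediction, Detection
    and Lateralization from Intracranial and Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint seizure prediction (pre-ictal state), detection, and
    left/right mesial-temporal lateralization from windowed multichannel
    EEG.  Non-overlapping 1-second windows of intracranial, scalp, or
    combined EEG are converted to dense weighted similarity graphs
    (Pearson correlation, histogram mutual information, or a Waxman
    distance-decay model) whose vectorized adjacency matrices feed
    shallow, convolutional, or LSTM neural-network classifiers trained
    with Adam.  Includes EDF input/output with a JSON seizure-annotation
    sidecar, montage assembly with zero-padding for unilateral implants,
    class extraction at a fixed 4:3:2 non-seizure/pre-seizure/seizure
    ratio over a 10-minute pre-ictal horizon, patient-held-out and
    patient-agnostic cross-validation, surface-negative and
    lateralization analyses, and a synthetic simultaneous scalp+iEEG
    cohort generator for end-to-end testing without patient data.
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
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
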