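Package: voxcog
Title: Dementia Screening from Long Neuropsychological-Exam Voice Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for screening dementia from hour-scale audio
    recordings of neuropsychological examinations. Audio is converted to
    13-dimensional Mel-frequency cepstral coefficient (MFCC) sequences and
    classified by either a two-level hierarchical long short-term memory (LSTM)
    network or a variable-length one-dimensional convolutional network with
    global average pooling, both implemented natively with full backpropagation
    and Adam training. The convolutional model yields temporal saliency tracks
    (position-wise class evidence whose mean is the recording-level logit),
    from which salient administered fractions (SAF) are computed per
    neuropsychological test. Includes cognitive-status labeling from diagnosis
    timelines (180-day rule), participant-level cross-validation splits, a full
    binary-classification metric suite (ROC/PR AUC, balanced accuracy, MCC),
    test-duration comparisons, and a synthetic exam-cohort generator that
    emulates two-speaker exam audio with class-conditional timing and acoustic
    effects so the entire pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
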