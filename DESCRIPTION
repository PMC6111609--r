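Package: callscore
Title: Two-Stage Bioacoustic Call Classification from Classifier Score Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies animal vocalizations recorded by acoustic sensors in
    two stages. Frames of a recording are represented by HTK-dialect
    mel-frequency cepstral coefficients (MFCC) and labelled by a pluggable
    supervised frame classifier; the per-class score series the classifier
    emits are then summarized by linear-frequency cepstral coefficients
    (LFCC) and classified by a second-stage classifier, replacing the naive
    frame-counting rule that fails on short calls embedded in noise.
    Includes a synthetic anuran-call generator with region-of-interest
    annotations, ten macro-averaged multiclass performance metrics,
    rotating k-fold cross-validation, a joint classifier grid sweep, and
    bootstrap confidence intervals with paired outperformance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    mclust,
    nnet,
    rpart
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
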