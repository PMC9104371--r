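Package: sentitri
Title: Three-Class Sentiment Trichotomization for Open-Ended Survey Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for sentiment analysis of free-text survey
    responses collected during COVID-19 lockdowns. Text is scored on [-1, 1]
    by an embedding-based regressor (a small feed-forward network or a
    support-vector regressor trained on a binary-polarity corpus), the score
    is trichotomized into negative/neutral/positive through two decision
    thresholds calibrated by 5-fold cross-validated grid search, and results
    are evaluated with weighted one-vs-all metrics over confusion matrices in
    the rows-predicted/columns-real convention. Includes a synthetic-data
    generator that emulates the stratified survey corpus and the binary
    training corpus, frequency-thresholded word-cloud summaries, and a
    verification command that recomputes the published reference metrics from
    the bundled confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
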