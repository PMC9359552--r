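Package: congestr
Title: Measuring Congestion from Player Tracking Data in Australian Football
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies congestion in Australian football from 10 Hz player
    tracking and match event streams. Provides a per-frame density-clustering
    pipeline (OPTICS ordering with an epsilon-threshold extraction) that labels
    each of the 36 on-field players as being in primary, secondary, or outside
    congestion and aggregates the proportions by field zone and quarter; a
    disposal-level congestion classifier built on nine spatiotemporal features
    around the ball-carrier with a Random Forest and a full evaluation report
    (precision, recall, F1, confusion matrix, one-vs-all ROC-AUC and PR-AUC);
    and a synthetic match and disposal generator with planted ground truth so
    every stage is testable without proprietary tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
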