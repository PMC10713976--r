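Package: rtalign
Title: Retention-Time Alignment of LC-MS Feature Lists with a Learned
    Pair Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns MS1 feature lists (m/z, retention time, intensity,
    charge) across LC-MS runs. A coarse piecewise retention-time
    correction against an anchor run is followed by a feed-forward
    neural classifier that scores candidate feature pairs encoded as
    40-value normalized context vectors; accepted pairs are assembled
    into cross-run feature groups with a decoy-based false discovery
    rate estimate. Includes readers for common feature-table dialects
    (generic CSV/TSV, MaxQuant allPeptides, Dinosaur, OpenMS
    featureXML), a simulated retention-time-shift benchmark generator
    with ground truth, and precision/recall evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
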