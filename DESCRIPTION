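Package: cpscreen
Title: Analysis Pipeline for Activated Cell Painting Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-content Cell Painting screens run in
    resting and activated cell states. Converts per-cell morphological
    feature tables into per-well HistDiff fingerprints against same-plate
    reference controls (with block normalization for plate staining
    stripes), computes CP Activity Scores and activity thresholds (IQR,
    FDR, elbow), runs plate quality-control gates (brightfield activation
    classifier, paired-condition comparison, control-anomaly decisions,
    replicate-control reproducibility), performs feature reduction and
    density-based and hierarchical clustering, target-class enrichment and
    consolidation-entropy analysis, and glucocorticoid-receptor nuclear
    translocation scoring. Includes a seeded synthetic-screen generator
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
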