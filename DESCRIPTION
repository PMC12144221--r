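Package: phantomqc
Title: Phantom-Based Consistency Testing of Lesion-Detection AI in CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies AI-generated colour heatmap labels from repeated CT
    angiography phantom acquisitions and measures how consistently a
    lesion-detection algorithm responds to changes in radiation dose and
    image reconstruction. Implements blue-channel threshold segmentation of
    8-bit RGB heatmap overlays, connected-component label extraction with
    physical size and inverted-grayscale intensity metrics, geometric
    matching of labels to ground-truth lesions with per-scan triage
    decisions, coefficient-of-variation reproducibility analysis restricted
    to fully reproducible dose cells, a parallel human-reader visual-grading
    arm, and Mann-Whitney U comparisons with Bonferroni correction. A
    synthetic-study generator emulates a full dose-by-reconstruction-by-
    repetition phantom experiment so the entire pipeline runs and is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
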