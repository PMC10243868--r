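Package: cellsieve
Title: Weakly Supervised Multi-Type Cell Detection Toolkit for Partially
    Annotated Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic building blocks for multi-type cell detection
    and differential counting on partially annotated whole-slide images:
    cascade-stage sample selection with dual-layer filtered negative instance
    sampling, soft-sampling attention weights, single- and multi-class
    non-maximum suppression with a brute-force oracle, Jaccard-gated patch
    augmentation and histogram-specification color normalization, an adaptive
    data-oriented learning-rate schedule, two-level ROI coordinate mapping,
    detection evaluation (recall/precision/F1, confusion matrices), bone
    marrow nucleated differential cell counts with the 500-cell adequacy rule,
    and Cohen's kappa observer agreement. A deterministic synthetic slide and
    proposal simulator exercises every component without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
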