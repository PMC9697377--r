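Package: pestdetectr
Title: Deformable-Convolution and Attention Feature-Pyramid Detection of Crop Pests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage convolutional object detector for multi-scale crop-pest
    imagery, built from first principles: deformable 2-D convolution with explicit
    bilinear sampling inside a small residual backbone, an attention-weighted
    multi-scale feature-fusion pyramid neck (a feature pyramid network whose
    per-level fusion factor is a learned sigmoid weight map), a region proposal
    network with class and box-regression heads, and the full evaluation stack
    (intersection-over-union matching, precision/recall sweeps, average precision
    and mean average precision). Includes Pascal VOC XML annotation input/output,
    dataset splitting and statistics, and a seeded synthetic pest-scene generator
    that emulates the small relative sizes, class imbalance, occlusion and dense
    layouts typical of field-collected pest datasets, so the whole detection
    pipeline is testable end-to-end without external data. All network layers
    carry hand-derived gradients over compiled kernels; no external deep-learning
    framework is used.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    png,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
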