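Package: phdseg
Title: Perception-Guided Evaluation and Training for Membrane Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating and training thin-structure (cell membrane)
    segmentations in a way that tracks human judgement. Implements the
    perceptual Hausdorff distance, a point-set metric between skeletonized
    segmentations with a tolerance threshold below which small misalignments
    are forgiven; a suite of classical pixel, distance, topology and region
    metrics with optional skeletonization; a two-alternative forced-choice
    harness scoring metric agreement with recorded human preferences;
    skeleton-aware training losses with a coarse-to-fine weight schedule; a
    compact two-branch (global-local) encoder-decoder segmentation pipeline;
    and a deterministic generator of synthetic membrane phantoms with
    controlled perturbations for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
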