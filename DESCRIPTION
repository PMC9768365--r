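Package: noduleval
Title: Standardized Evaluation of Pulmonary Nodule CAD Detection Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A third-party-style evaluation framework for computer-aided
    detection (CAD) algorithms for pulmonary nodules. Matches
    algorithm-predicted bounding boxes against multi-slice reference-standard
    annotations under three mark-labeling rules (center hit, center distance
    with an adaptive per-nodule radius, and area overlap), performs greedy
    one-to-one assignment with deterministic tie-breaking, computes recall,
    precision and F1 with TP/FP/FN accounting, stratifies miss rates by
    nodule type and size bin, statistically compares matching rules across
    algorithms (one-way ANOVA, pairwise t-tests, significance labels), scores
    annotator qualification and three-reader consensus merging, and ships a
    synthetic dataset generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
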