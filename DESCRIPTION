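Package: fallhmm
Title: Silhouette-Based Fall Detection with a Two-State Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Video-vision fall monitoring for elderly-care applications.
    Detects the moving person in a frame sequence with a per-pixel
    mixture-of-Gaussians background model refined by graph-cut segmentation,
    summarises each silhouette by virtual-grounding-point features (point
    distance, area, aspect ratio), localises abrupt posture changes with a
    moving-average/modified-difference statistic and its full width at half
    maximum, and labels every frame abnormal (falling) or normal by Viterbi
    decoding of a supervised two-state discrete-emission hidden Markov model.
    Includes a synthetic scene generator with per-frame ground truth and a
    subcommand CLI covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
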