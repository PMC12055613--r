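Package: reachstart
Title: Upper-Limb Reaching Kinematics and StartReact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying upper-limb reaching after hemiparetic
    stroke from markerless video keypoint tracks. Computes the Index of
    Elbow Extension (IoEE) from 2D DeepLabCut-style keypoint tracks,
    validates it against elbow angles derived from 3D joint coordinates,
    detects EMG response-onset latencies with a baseline-threshold rule to
    quantify the StartReact effect (the shortening of reaction time by a
    startling sound), and runs a Spearman correlation battery with
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    data generator (articulated two-segment arm, surface EMG trials, and
    patient cohort tables with a shared latent severity) so every stage of
    the pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
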