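Package: fbbc
Title: Feature-Based Behavior Coding from Pose-Estimation Keypoint Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for feature-based behavior coding (FBBC) of
    pose-estimation keypoint time series. Reads DeepLabCut keypoint files and a
    native columnar track container, derives interpretable kinematic features
    (positions, speeds, distances, dot and cross products of keypoint vectors),
    restricts analyses to labeled scenes, normalizes and concatenates feature
    series, thins and embeds them in two dimensions with UMAP, converts cluster
    assignments in embedding space into per-frame behavior-code timelines, and
    ships a regime-switching posture simulator so the whole pipeline is testable
    without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
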