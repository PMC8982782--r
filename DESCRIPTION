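Package: attendr
Title: Attention Recognition from Facial Landmark Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognises visual attention versus inattention from streams of 34
    tracked facial landmarks, as produced by consumer face-tracking SDKs during
    a continuous performance task (CPT). Implements pairwise Euclidean distance
    features, a distance-threshold feature-selection procedure based on
    per-class mean distances, an RBF-kernel support vector machine classifier
    and a small convolutional network over landmark raster images, together
    with participant-specific, leave-one-participant-out and bidirectional
    cross-group evaluation protocols. A synthetic landmark-stream simulator
    with head-yaw-driven pose shifts and full ground truth makes every stage
    testable without access to human video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
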