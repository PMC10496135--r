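Package: PostureSeg
Title: Unsupervised Posture Segmentation of 3D Pose-Tracking Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Converts per-frame 3D pose-estimation output for freely moving
    mice into frame-by-frame behavioral-module labels. Vertical (z)
    coordinates of six bodily hotspots are transformed into signed pairwise
    height differences, clustered per subject into postures with an
    elbow-criterion k-means, matched across subjects into cohort-level
    behavioral modules, and mapped back onto every frame. Includes bout
    (run-length) duration analytics, session-normalization scores for
    stimulus-evoked change, a correlation surface against manually scored
    ethograms, and a synthetic cohort generator with planted posture
    archetypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), mclust, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
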