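Package: kinescore
Title: Biomechanical Scoring of 2D Pose Keypoint Time Series for Physiotherapy Assessment
Version: 0.1.0
Authors@R: person("Kinescore", "Developers", email = "kinescore@example.org", role = c("aut", "cre"))
Description: Turns 2D skeletal keypoint time series (COCO-17 layout, YOLO-pose
    text records or CVAT annotations) into biomechanical parameters and
    normalized clinical mobility scores. Provides a three-stage pipeline:
    keypoint I/O and validation, kinematic analysis (joint and segment angles,
    time-in-range, angular velocity and acceleration, postural sway) gated by
    a learned body-orientation classifier (Frontal/Turned/Profile), and a
    scoring layer that maps ranges of motion to per-parameter scores,
    traffic-light statuses, body-part and global mobility scores, and
    clinical-scale sub-reports. Includes a synthetic articulated-skeleton
    motion generator with ground-truth angles and orientation labels so every
    stage is testable without video or a trained pose network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    FNN,
    quadprog,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
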