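Package: kinemotion
Title: Kinematic Feature Extraction for Emotional Full-Body Movement
Version: 0.1.0
Authors@R:
    person("Movement", "Kinematics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying emotional expressivity in full-body
    movement recordings. Reads inertial motion-capture exports (an
    MVNX-style XML dialect with 23 body keypoints), converts them to
    tabular per-keypoint time series and camera-relative screen
    coordinates, and computes twelve kinematic features (speed,
    acceleration, angular speed, angular acceleration, limb contraction,
    distance to center of mass, quantity of motion, dimensionless jerk,
    head tilt with respect to back and to vertical, and 2D/3D convex
    hulls) summarised into thirty-two per-sequence statistics. Includes a
    silhouette-video module (Boolean mask stacks, silhouette motion
    masks, foreground statistics), a deterministic synthetic generator of
    emotion-modulated choreography for end-to-end testing without
    proprietary hardware, and observer-rating utilities (confusion
    matrices, recognition summaries, chance-level tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
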