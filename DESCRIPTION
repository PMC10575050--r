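Package: rehabtrack
Title: Trajectory Reconstruction, Quality Scoring and Classification of
    Rehabilitation Exercises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring musculoskeletal-rehabilitation exercises
    from four classes of motion-tracking hardware. Reconstructs metric 3-D
    target-point trajectories from inertial streams (dead reckoning with an
    optional linear Kalman filter), motion-capture suits (forward kinematics
    over a sized skeleton), and camera keypoints (orthogonal two-camera
    scaling or general DLT triangulation); scores exercise executions against
    fitted references with a four-component quality score (trajectory
    deviation, duration, spatial limits, mean speed); and classifies
    exercises from sliding-window trajectory fragments with tree, ensemble,
    nearest-neighbour and neural-network backends. A synthetic-data module
    generates ground-truth exercises and simulates every sensor class so all
    pipelines can be exercised end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    class,
    rpart,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
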