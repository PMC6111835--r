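Package: rehabmotion
Title: Exercise Analysis for Skeleton-Tracking Rehabilitation Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates rehabilitation exercises (elbow and knee
    flexion-extension, step climbs, multi-directional balance) from
    25-joint skeletal position time series of the kind produced by
    depth-camera body tracking. Computes joint angles from adjacent
    segment vectors, estimates the body center of mass from an
    anthropometric segment-mass table, counts repetitions with a
    two-threshold hysteresis automaton, detects step climbs from hip
    elevation combined with knee cycles, and scores an eight-direction
    balance protocol by time on target. Includes a deterministic
    synthetic motion generator emulating a 30 Hz skeletal stream,
    canonical CSV/JSON session formats, achievement-rate aggregation,
    report generation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
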