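Package: gazeqc
Title: Eye-Tracker Test-Battery Analysis and Synthetic Dual-Tracker Gaze Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating eye-tracking data quality with a multi-task
    test battery. Classifies blinks, saccades, microsaccades and fixations with
    a velocity-threshold (elliptic lambda-criterion) algorithm, computes spatial
    accuracy and precision in spherical visual degrees with winsorized robust
    aggregation, models smooth-pursuit onset latency and tracking velocity with
    a Bayesian hinge (changepoint) regression, normalizes pupil-area responses
    to luminance steps, synchronizes clocks across simultaneously recorded
    trackers, and generates the battery's target schedules. A synthetic
    dual-tracker gaze simulator (one constant-rate monocular stream, one fused
    from two phase-offset cameras) provides ground truth for recovery testing
    of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
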