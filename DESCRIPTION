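Package: soundframes
Title: Coordinate-Frame Inference for Auditory Spatial Receptive Fields in
    Freely Moving Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to resolve the coordinate frame (egocentric, head-centered,
    versus allocentric, world-centered) of spatial receptive fields recorded
    from freely moving observers. Provides head-pose geometry and LED-tracking
    calibration, deterministic simulated receptive fields and their predicted
    tuning under arbitrary behavior, a synthetic session generator (trajectories,
    click schedules, Poisson spike trains), tuning-curve estimation with
    modulation depth and classical receptive-field metrics, a residual-modulation
    statistical framework with simultaneous prediction intervals, single-trial
    Poisson GLM model comparison with AIC classification and shuffle controls,
    time-resolved model fits with cluster-based permutation statistics,
    distance- and speed-resolved analyses, and waveform-based tracking of unit
    identity across sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
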