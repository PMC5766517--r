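Package: speakr
Title: Hidden Speed Micro-Fluctuation Biomarkers from Reaching Kinematics
Version: 0.1.0
Authors@R:
    person("speakr", "developers", email = "speakr@example.org", role = c("aut", "cre"))
Description: Extracts hidden speed micro-fluctuations (s-Peaks) from 3D hand
    trajectories recorded during repetitive reach-to-touch tasks, quantifies
    their departure from full temporal randomness with a scalar biomarker (the
    R-parameter, the interval-weighted non-exponential mass of the
    speed-inter-peak-interval distribution), and classifies recordings in
    R-space with a logistic model. Includes triangular FIR smoothing with exact
    frequency-response analysis, movement-cycle segmentation from reach
    trajectories, a minimum-jerk simulator with additive white Gaussian noise
    at controlled SNR for validating the statistic, and a command-line
    interface for reproducible batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
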