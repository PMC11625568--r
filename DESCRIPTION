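Package: kinegait
Title: Markerless Gait Analysis from a Single RGB-D Camera Skeleton Stream
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatio-temporal gait parameters and per-cycle center-of-mass
    excursions from skeletal joint trajectories recorded by an RGB-D depth camera
    with body tracking (Azure-Kinect-style 30 fps streams), for healthy and
    hemiplegic walkers. The pipeline resamples joint trajectories to a uniform
    50 Hz grid with cubic interpolation, applies a zero-phase third-order 5 Hz
    Butterworth low-pass filter, labels each ankle stance or swing by a 2 cm
    depth-delta threshold, extracts gait events inside a virtual gait-analysis
    path, and derives stride, step, double-support, foot-off, speed and cadence
    measures plus medio-lateral, vertical and antero-posterior CoM sway.
    Includes method-comparison statistics against a reference motion-capture
    system (paired t, accuracy as 100 minus MAPE, Pearson r, RMSE, Bland-Altman
    limits of agreement) and a synthetic skeletal-gait simulator with known
    ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
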