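Package: imugait
Title: Calibration-Free Gait Analysis from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gait events (initial contact, full contact, heel rise,
    toe-off) and bilateral gait phases from raw gyroscope and accelerometer
    recordings of two foot-worn inertial measurement units, without any
    sensor-to-foot calibration or magnetometer. Orientation is estimated by
    quaternion strapdown integration of the angular rates with
    accelerometer-based inclination correction; per-stride zero-velocity-anchored
    double integration with linear drift correction yields stride length and
    walking speed. Relative durations of loading response, single limb support,
    mid-stance, terminal stance, pre-swing and swing, cadence and trial-level
    summaries are reported per foot. A kinematically consistent two-foot gait
    simulator with exact ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
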