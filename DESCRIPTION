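Package: turnmetry
Title: Turning Angle and Angular Velocity Estimation from 3D Skeleton Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies turning movements from 3D human pose (skeleton)
    time series, as used in video-based gait analysis of Parkinson's
    disease. Computes cumulative turning angle from ground-plane hip,
    knee and shoulder joint-pair vectors, angular speed and maximum
    angular velocity, quantises angles into 45-degree clinician-style
    bins, segments turning episodes from continuous skeleton streams,
    scores predictions against annotations (accuracy, mean absolute
    error, weighted precision, Cohen's kappa), and runs per-subject
    PD-versus-control group comparisons. Includes an articulated
    synthetic-motion simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
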