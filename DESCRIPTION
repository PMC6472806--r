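Package: fishtrack
Title: Behavioral Tracking and Closed-Loop Stimulation for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Fishtrack", "Developers", email = "fishtrack@example.org",
           role = c("aut", "cre"))
Description: Computational core for video-based behavioral tracking of larval
    zebrafish and closed-loop visual stimulation. Provides online extraction of
    tail, eye and whole-body kinematics from grayscale image sequences
    (tail skeletonization by center-of-mass or arc sampling, moment-based eye
    ellipse fitting, background-subtraction blob tracking with identity
    maintenance and Kalman smoothing), behavior-state estimators (swim vigor,
    vigor-based forward velocity), closed-loop stimulus-velocity laws,
    camera-to-display affine calibration, timed stimulus protocols executed
    against a real or simulated clock with full parameter and event logging,
    and a seed-deterministic synthetic-fish renderer that supplies ground
    truth for every tracker.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    rhdf5,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
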