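Package: myointent
Title: Myoelectric and Load-Cell Intent Classification for the Hemiparetic Shoulder and Elbow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline pattern-recognition pipeline for predicting intended
    isometric shoulder and elbow torque direction from multi-channel surface
    EMG and six degree-of-freedom load-cell recordings, as used in studies of
    abnormal flexion/extension synergy after stroke. Provides power-line notch
    filtering, rigid-body conversion of load-cell forces and moments to joint
    torques, maximum-voluntary-torque estimation, threshold-based trial
    segmentation, overlapped sliding-window extraction of Hudgins time-domain
    EMG features and window-mean torque features, a pooled-covariance linear
    discriminant classifier, trial-wise leave-one-out cross-validation with
    confusion matrices and per-class accuracies, and a synthetic-trial
    generator with a tunable abnormal-synergy coupling parameter so the whole
    analysis runs without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    MASS
Config/testthat/edition: 3
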