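Package: eogaze
Title: Gaze-Motion Tracking from Electrooculography with Quadrant Affine
    Calibration and Planar Robot Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning two-channel electrooculogram (EOG) recordings
    into on-screen gaze positions and joint angles for a two-link planar robot
    manipulator. Saccade waves are extracted with a 60 Hz second-order low-pass
    filter, threshold/polarity detection and a full-wave signal integral whose
    magnitude is linear in gaze distance; normalized integrals are mapped to
    pixel displacements through per-direction linear gains. Systematic
    distortion of the estimated gaze points is corrected with a per-quadrant
    factored affine transform (translation, rotation, back-translation, shear,
    dilatation) fitted on a 24-target calibration grid, and corrected gaze
    points are converted to shoulder/elbow angles by closed-form inverse
    kinematics. A synthetic-signal generator with known ground truth makes
    every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
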