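Package: arm7ik
Title: Upper-Limb Joint Reconstruction from an End-Effector Robot and One
    Accelerometer
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs the seven joint angles of the human arm (shoulder
    abduction-adduction, flexion-extension and internal-external rotation,
    elbow flexion-extension, forearm pronation-supination, wrist
    ulnar-radial deviation and flexion-extension) during rehabilitation
    therapy assisted by an end-effector robot, using only the robot hand
    pose, the shoulder position and a single accelerometer strapped to the
    upper arm.  Implements a seven degree-of-freedom Denavit-Hartenberg arm
    model, closed-loop inverse kinematics on the augmented (geometric plus
    swivel-angle) Jacobian with damped least-squares inversion, elbow
    localization from the accelerometer gravity vector, a closed-form
    initial-pose solver, a synthetic motion and sensor simulator for
    validation by parameter recovery, and session evaluation metrics
    (RMSE, SD, Pearson correlation, range of motion).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
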