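Package: gaitrec
Title: IMU Gait Recognition and Exoskeleton Assistance Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wearable-sensor gait analysis aimed at soft hip-assist
    exoskeleton control: simulation of two-leg inertial measurement unit (IMU)
    gait signals with known ground-truth events, rule-based detection of heel
    strike, toe off and maximum hip flexion from foot and thigh gyroscopes,
    motion-state recognition over ten road conditions with a binary-tree
    composition of radial-basis-function support vector machines, gait-phase
    recognition with a long short-term memory (LSTM) sequence classifier, and
    event-anchored planning of the assistance-force profile applied during the
    swing phase. Includes evaluation utilities (accuracy, macro-F1, multiclass
    Matthews correlation, column-normalized confusion matrices, subject-wise
    splits and cross-validation) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
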