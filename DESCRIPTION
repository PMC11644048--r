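Package: propoint
Title: Webcam-Based Assessment of Upper-Extremity Proprioception from Hand
    Landmark Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to score finger-to-finger pointing tests of upper-extremity
    proprioception from 21-landmark hand-pose streams recorded with a webcam.
    Provides a validated stream data model with JSONL/CSV I/O, hand-size-based
    pixel-to-centimeter calibration, frontal-plane pointing-error series,
    automated movement-stop detection, randomized pointing protocols,
    cohort-level scoring with outlier removal and normative flags, a simulator
    of the robotic Crisscross finger-crossing assessment for concurrent
    validation, and synthetic landmark-stream generators with known ground
    truth so every stage is testable without a camera or human subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
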