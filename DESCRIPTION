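Package: etbids
Title: Convert, Validate and Simulate Eye-Tracking Recordings in BIDS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for organizing eye-tracking recordings (gaze position and
    pupil size) under the Brain Imaging Data Structure (BIDS). Parses the
    EyeLink ASC plain-text export dialect, converts sessions into compliant
    physio/physioevents TSVGZ files with sidecar JSON metadata, validates
    existing BIDS trees against the eye-tracking rules (PhysioType "eyetrack",
    RecordedEye, SampleCoordinateSystem, OnsetSource, uniform sampling, column
    contracts), and simulates synthetic monocular or binocular sessions with
    fixations, saccades, blinks and pupil drift so the whole pipeline can be
    exercised without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
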