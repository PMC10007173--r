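Package: lapskill
Title: Autonomous Assessment of Laparoscopic Hand Movements with a
    Cascaded Fuzzy Supervisor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grades laparoscopic box-trainer hand movements from
    dual-camera (top and front view) instrument detections. Bounding-box
    centroids are calibrated from pixels to centimetres, reduced to the
    distance from the field-of-interest centre (top view) and the
    instrument height (front view), and fed to a two-level cascaded
    Mamdani fuzzy inference system that produces per-hand performance
    scores (SRHPA, SLHPA) and a final performance assessment (FPA) on a
    0-100 per-cent scale with letter grades A-E. Includes a generic
    Mamdani engine with singleton fuzzification and centroid
    defuzzification, detection-stream readers and writers (JSON Lines
    and CSV), frame pairing across cameras, session aggregation, and a
    seeded synthetic-session generator with expert and novice skill
    profiles so the whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
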