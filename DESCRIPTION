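Package: PenTrack
Title: Tracking-by-Detection and Activity Scoring for Group-Housed Pigs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A detector-agnostic toolkit that turns per-frame posture
    detections of group-housed pigs (standing, sternal-lying,
    lateral-lying bounding boxes) into individual and group activity
    profiles. It links detections into identity-preserving tracks with a
    constant-velocity Kalman filter and Hungarian assignment on IoU cost,
    scores postures, walking bouts, distance and speed per pig and per
    group, deduplicates near-identical frames with a 64-bit perceptual
    hash, and evaluates detection (Pascal-VOC average precision) and
    tracking (CLEAR-MOT MOTA/MOTP) quality. A seeded top-view pen
    simulator with Markov posture switching, random-walk locomotion,
    feeder occlusion and a detector noise model provides ground truth so
    the whole pipeline is testable without video or trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    xml2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
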