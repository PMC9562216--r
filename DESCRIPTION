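Package: gaitevents
Title: Automatic Gait-Event Detection from Foot-Marker Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects initial-contact (IC) and toe-off (TO) gait events from
    the 3D kinematics of four foot markers (HEE, TOE, HLX, PMT5), as recorded
    by optical motion-capture systems during clinical gait analysis.
    Provides trial input/output for C3D files and delimited marker tables,
    derivation of ground-truth events from vertical ground-reaction-force
    traces by threshold crossing, Gaussian encoding of nominal event times
    into per-frame probability targets, a bidirectional LSTM sequence
    labeller trained with Adam and a weighted cross-entropy loss,
    peak-based event extraction from the network's score curve, and a
    temporal-tolerance evaluation protocol (recall, precision, false-alarm
    rates, error percentiles, trimmed-mean timing errors) stratified by
    heel-strike, midfoot, and forefoot initial-contact patterns.  A
    synthetic pathological-gait simulator with exact ground truth makes
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
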