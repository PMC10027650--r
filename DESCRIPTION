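Package: mirrorkit
Title: Virtual-Mirror Experiment Toolkit for Enfacement Research
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A feed-forward message-passing pipeline for virtual-mirror
    (enfacement) experiments: synthetic head-pose and action-unit streams,
    experimental-condition manipulators (delay buffering, expression
    amplification, pose/expression gating, baseline replay), a deterministic
    schematic avatar renderer, end-to-end latency calibration by sub-sequence
    cross-correlation of yaw tracks, an experiment session interface with
    counterbalanced induction schedules, and weighted sense-of-agency scoring
    with principal-component loadings and Tucker congruence invariance checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
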