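Package: ergowear
Title: Ergonomic Posture Scoring and Joint Kinematic Wear from Joint-Angle Time Series
Version: 0.1.0
Authors@R: person("ergowear", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Sample-wise ergonomic risk assessment of wearable motion-capture
    joint-angle time series. Implements two finite-state-machine scoring
    methods: LUBA (Postural Loading on the Upper Body Assessment), which maps
    back, shoulder and elbow joint-motion angles to integer discomfort scores
    and a global corrective-action category, and AWBA (Agricultural Whole-Body
    Assessment), which combines upper-limb (AULA) and lower-limb (ALLA) risk
    levels through a rule grid. A per-joint-motion kinematic wear index with
    RC-circuit-like exponential wear and recovery dynamics accumulates postural
    hazard over time. Per-window posture labels link risk to posture classes
    in machine- and human-readable work-shift reports. Includes a synthetic
    trial generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
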