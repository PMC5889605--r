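Package: emgmodes
Title: Gait-Cycle-Referenced Surface EMG Mode Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments motion cycles of treadmill locomotion from vertical
    hoof-marker kinematics, conditions raw surface electromyography
    (DC removal, full-wave rectification, decimation to 120 Hz, zero-phase
    fourth-order 20 Hz Butterworth low-pass, per-electrode per-session
    maximum normalization), pools the ten highest envelope peaks per motion
    cycle, fits a one-dimensional Gaussian mixture over peak phases by
    expectation-maximization to obtain mean mode locations and mean mode
    values split by stance and swing phase, and runs normality-routed
    paired and repeated-measures comparisons with Bonferroni correction
    plus Cronbach's alpha test-retest reliability across data-collection
    days. Includes a synthetic-data generator emulating cyclic hoof
    displacement and burst-amplitude-modulated surface EMG so the whole
    pipeline is testable without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
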