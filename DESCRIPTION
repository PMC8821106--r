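Package: slopegait
Title: Gait Stability and Margin-of-Stability Analysis for Rolling-Hills Treadmill Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying gait stability on continuously varying mild
    slopes. Generates a sum-of-sines "rolling hills" platform pitch signal,
    simulates treadmill walking trials with known ground truth, and analyses
    the kinematics: zero-lag Butterworth filtering, velocity-based
    heel-strike/toe-off detection, spatiotemporal step measures, the
    mediolateral margin of stability from the extrapolated centre of mass,
    trunk posture and trunk-acceleration measures, uphill/downhill step
    classification, and two-way repeated-measures ANOVA with sphericity
    diagnostics, Greenhouse-Geisser correction, partial eta squared, and
    Bonferroni post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
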