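Package: pairedslip
Title: Coupled Spring-Loaded Inverted Pendulum Models and Gait
    Synchronization Analysis for Paired Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how two walkers adapt and synchronize their
    gaits when mechanically coupled through a carried object. Provides a
    sagittal-plane hybrid-dynamics simulator of two spring-loaded inverted
    pendulums (SLIPs) joined by spring-damper arms to a carried mass, with
    event-driven support-state switching, apex return maps, periodicity
    scoring and a three-step systematic parameter search; and an analysis
    pipeline for motion-capture-style trajectory tables covering heel-strike
    detection, gait cycle time, step length, forward velocity,
    cross-correlation phase lags, quadrupedal footfall-pattern
    classification, interlimb coordination and Procrustes-style curve
    dissimilarity. A synthetic-trial generator with ground truth makes the
    full pipeline testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
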