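Package: motionfc
Title: Motion-Inclusive Functional Connectivity and Brain-Behavior Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Head-motion-aware estimation of resting-state functional
    connectivity and brain-wide association statistics. Implements framewise
    displacement from rigid-body realignment parameters, motion scrubbing with
    configurable censoring windows, motion-ordered (minTP-matched) and
    bootstrap-aggregated (bagged) connectivity estimation, edgewise partial
    Spearman brain-behavior scans with Benjamini-Hochberg false-discovery-rate
    edge selection, bootstrap sampling-variability curves across
    logarithmically spaced sample sizes with AUC-based method comparison, and
    Lin's concordance correlation coefficient for paired method agreement. A
    synthetic cohort generator with group-dependent motion distributions,
    motion-inflated connectivity, and a planted edge-behavior effect makes the
    full pipeline testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
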