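Package: wigwag
Title: Binocular Phototaxis Simulation and Trajectory Statistics for
    Planarian Photo-Response Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation and analysis of planarian negative
    phototaxis. Models the two clamped-sine eye inputs created by the
    binocular visual field, a threshold-gated proportional turning rule,
    and stochastic "wigwag" head self-motion with normal swing angles and
    log-normal inter-event intervals. Provides closed-form optics of the
    front blind-like spot and response band, exceedance and turn-away-time
    calculations, an event-driven arena simulator for one- and two-source
    orientation assays with per-eye perturbation models, circular and
    trajectory statistics (mean resultant length, precision index, escape
    value, twin-tail separation, rose binning), maximum-likelihood fitting
    of wigwag distributions, and a synthetic video-tracking fixture
    generator with TSV import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse
Config/testthat/edition: 3
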