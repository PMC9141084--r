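Package: greengame
Title: Tripartite Evolutionary Game for the Green Transformation of
    Anti-Epidemic Supplies
Version: 1.0.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a three-population evolutionary game between
    governments (regulate vs. deregulate), mask enterprises (increase vs.
    not increase production of environmentally friendly masks), and medical
    institutions (use environmentally friendly vs. regular disposable
    masks).  Provides the per-strategy payoff matrix, expected utilities,
    replicator dynamics, analytic Jacobian with eigenvalue classification
    of the eight pure-strategy equilibria, policy thresholds (regulation
    indifference proportions, critical reputation loss, midpoint region
    proportions), finite-difference sensitivity signs, a fixed-step
    Euler/RK4 simulator with mid-run policy interventions, scenario and
    parameter-sweep presets, and a command-line interface for reproducible
    reports.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
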