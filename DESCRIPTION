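Package: ctxgate
Title: Simulation and Analysis of Context-Gated Pavlovian Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analyzing bidirectional occasion-setting
    (context-gated reward prediction) experiments in conditioning chambers.
    Generates session schedules for four Pavlovian discrimination tasks
    (context-dependent single outcome, simple discrimination, no
    discrimination, context-dependent dual outcome), renders timestamped
    event logs (context transitions, cue on/off, rewards, port entries and
    exits), and provides synthetic-behavior generators: Rescorla-Wagner
    style elemental (summation) and hierarchical (context-gated) learning
    agents, and a parametric responder with sex-dependent acquisition,
    prior-reward history effects, and acute-stress decrements. Analysis
    functions compute time in port, response probability, discrimination
    ratios, discriminator classification and sessions to criterion,
    within-session trial-history stratification, stress difference scores,
    longitudinal mixed-model orchestration, and c-Fos density comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    car,
    nlme,
    withr,
    rlang,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
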