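Package: griplift
Title: Precision Grip-Lift Force Analysis Across Gravitoinertial Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for precision grip-lift trials recorded under
    changing gravitoinertial load, from raw grip-force, load-force and
    acceleration traces to trial metrics and session-level indices.
    Provides zero-phase low-pass filtering and finite-difference force rates,
    rule-based detection of force onsets, lift-off and trial end, plateau
    estimation, exponential grip-force decay fits, lagged cross-correlation
    coupling between grip and load force rates, switching indices across
    gravity transitions, and a decomposition of the grip-force switch into a
    predictive gain term and a safety margin. A synthetic trial generator
    with full ground truth emulates the grip-lift structure of centrifuge
    sessions so every stage of the pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
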