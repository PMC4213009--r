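Package: minimizr
Title: Covariate-Adaptive Minimization and Randomization for Two-Arm Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for allocating participants to the control or
    experimental arm of a two-arm clinical trial by covariate-adaptive
    minimization in the tradition of Taves and Pocock-Simon, with a
    configurable biased-coin randomization element. Provides class-vector
    construction over prognostic factors (gender, age class, diabetes,
    aggregated ethnicity by default), marginal-total aggregation of the
    allocation history, score-based arm selection, a durable delimited
    plain-text state file with a mirrored archive and reconstruction from
    administrator backup messages, plain-text notification rendering, a
    simulation harness that quantifies arm balance against simple
    randomization, and a command-line front end for running a trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
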