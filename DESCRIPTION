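Package: deapanel
Title: Panel Data Envelopment Analysis with Super-Efficiency SBM, Malmquist
    Productivity Decomposition, and a Censored-Regression Second Stage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-stage efficiency analysis of balanced panels of
    decision-making units, as used in health-services research. Stage one
    measures cross-sectional efficiency with radial (CCR, BCC) and
    slack-based (SBM, super-efficiency SBM) data envelopment analysis
    models solved as linear programs, and tracks productivity over time
    with the adjacent-period Malmquist index decomposed into efficiency
    change, technical change, pure efficiency change, and scale efficiency
    change. Stage two regresses efficiency scores on environmental
    covariates with a two-limit censored-normal (Tobit) maximum-likelihood
    regression. Includes calibrated synthetic panel generators with known
    frontier structure so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
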