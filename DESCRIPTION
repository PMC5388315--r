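Package: thermaldev
Title: Temperature-Dependent Development Models for Insect Stage-Duration Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing constant-temperature rearing experiments on
    poikilotherm development. Reads stage-duration tables (mean development
    time, sample size and survival per life stage and temperature), converts
    durations to developmental rates, and estimates thermal parameters with
    the traditional degree-day and Ikemoto-Takai linear models (lower
    threshold and thermal constant with standard errors), three nonlinear
    thermal-performance curves (Analytis, Briere-2, Lactin-2) fitted by
    seeded multi-start bounded least squares, and the Sharpe-Schoolfield-
    Ikemoto thermodynamic model with its intrinsic optimum temperature.
    Includes an individual-level cohort simulator for parameter-recovery
    studies and report writers for publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    lhs,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
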