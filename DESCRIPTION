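Package: scfsolub
Title: Density-Based and Association Models for Drug Solubility in
    Supercritical Carbon Dioxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlates solid-solute solubility in supercritical carbon
    dioxide with the standard battery of semi-empirical density-based
    models (Chrastil, Mendez-Santiago-Teja, Bartle, Kumar-Johnston,
    Gordillo and twenty more) and with association-theory solid-liquid
    equilibrium models.  Provides multistart nonlinear fitting with an
    AARD or SSE objective, exact linear-least-squares sub-solvers, a
    five-statistic scorecard, sublimation/solvation enthalpy estimation
    from fitted 1/T coefficients, solubility crossover-pressure
    detection, isotherm self-consistency diagnostics, and a synthetic
    data generator for parameter-recovery studies.  Ships the published
    24-point Regorafenib monohydrate solubility dataset (308-338 K,
    120-270 bar) as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    lhs,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
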