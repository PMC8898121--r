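Package: ferrokin
Title: Free-Iron Toxicity Kinetics and Biophysics of Packed Red Blood Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ferrous-iron (Fe2+) toxicity
    on packed red blood cells in vitro. Implements spectral unmixing of
    hemoglobin derivatives (oxyhemoglobin, deoxyhemoglobin, methemoglobin) from
    visible absorbance spectra by nonlinear least squares with an optional
    scattering baseline; a closed-form mass-action kinetic model of
    Fenton-driven methemoglobin formation with steady-state analysis, numerical
    ODE cross-checks and parameter estimation from methemoglobin time courses;
    Hertz-contact estimation of membrane Young's moduli from atomic force
    spectroscopy force-indentation curves with distribution and exceedance
    statistics; solution-preparation arithmetic; and seeded synthetic-data
    generators that emulate every measurement type so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
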