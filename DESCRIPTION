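Package: seivdyn
Title: Dynamics of an SEIV Epidemic Model with Waning Vaccination and
    Nonlinear Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for a four-compartment SEIV
    (susceptible-exposed-infectious-vaccinated) ordinary differential
    equation model of childhood diseases with partial permanent immunity,
    disease-caused death and waning vaccine protection.  Provides the
    vector field and invariant-region checks, reproduction thresholds via
    the next-generation matrix, disease-free and endemic equilibria with
    case classification, local stability through the Routh-Hurwitz
    conditions of the factored characteristic polynomial, center-manifold
    analysis of the transcritical bifurcation at R0 = 1 (forward versus
    backward direction), Hopf bifurcation detection in the treatment rate,
    checkable sufficient conditions for global stability, and stiff-capable
    numerical simulation with convergence and oscillation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
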