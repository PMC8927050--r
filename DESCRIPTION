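Package: gelmech
Title: Two-Phase Mechanochemical Model of Cell-Seeded Gel Swelling and Contraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis library for a one-dimensional two-phase
    (polymer network + solvent) model of a cell-seeded gel immersed in a
    solvent bath. Flory-Huggins free energy supplies the osmotic chemical
    potentials, a Hill-form cell traction potential supplies the
    mechanochemical forcing, and the gel boundary moves with the polymer
    phase. Provides the dimensionless energetics, spatially uniform
    steady-state solving with linear-stability classification and
    bifurcation-curve tracing, closed-form short-time asymptotic solutions,
    and a moving-boundary Crank-Nicolson finite-difference solver on a mapped
    fixed domain, with mass auditing, steady-state and dissolution detection,
    and a registry of reference scenarios covering swelling, contraction,
    non-uniform equilibria and the oscillating swelling regime.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
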