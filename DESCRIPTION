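Package: gbmimmune
Title: Glioblastoma-Immune Dynamics: ODE Modelling, ABC Inference and
    eFAST Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a three-population ordinary differential equation
    model of glioblastoma growth under immune control, coupling tumor
    cells, activated T cells and myeloid-derived suppressor cells (MDSCs)
    through the PD-L1-PD-1 immune checkpoint and MDSC-mediated T-cell
    suppression.  Provides analytic equilibrium and stability
    diagnostics (tumor-free equilibrium, Jacobian eigenvalues, global
    stability bounds), one-parameter bifurcation sweeps, Approximate
    Bayesian Computation (ABC) rejection inference against longitudinal
    cell-count data, posterior-predictive envelopes, 1-Wasserstein
    fitting of parametric families to posterior samples, a from-scratch
    eFAST variance-based global sensitivity analysis, and a synthetic
    generator for murine-style cell-count datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
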