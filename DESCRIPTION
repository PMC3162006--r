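Package: phaseloop
Title: Graphical Model Reduction of Biochemical Networks by Phase-Plane
    Hysteresis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies timescale separation between pairs of species in a
    nonlinear biochemical reaction network as the hysteresis area enclosed by
    their normalized phase-plane loop under a transient stimulus, estimates
    explicit steady-state relationships between rapidly equilibrating species
    by a computational concentration-clamp procedure with nonlinear
    least-squares fitting (Hill, linear, exponential, power forms), and
    assembles reduced-order models in which fast differential or implicit
    algebraic states are replaced by the fitted explicit relations. Reduced
    models are scored against the original over stimulus protocols and
    perturbation scenarios, and a Jacobian eigenvalue/modal timescale
    decomposition is provided for comparison. Includes a three-species toy
    pathway, a synthetic stiff-cascade generator, a declarative plain-text
    model format with optional CellML import, and command-line style drivers
    for analysis, reduction and Jacobian reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
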