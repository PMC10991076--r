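Package: adhesim
Title: Multiscale Simulation of Non-Local Cell-Cell Adhesion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates self-adhesive cell populations across scales: a
    deterministic agent-based model of cells accelerating towards
    neighbours within a finite sensing radius, an optional velocity-jump
    process for reorientation along tissue fibers, subcellular cell
    adhesion molecule (CAM) binding kinetics governed by mass action, and
    the corresponding one-dimensional macroscopic integro-partial
    differential equation with myopic diffusion and non-local adhesion.
    The macroscopic solver uses an outer operator-splitting scheme that
    freezes the non-local adhesion flux over short time windows and
    advances the remaining advection-diffusion problem with a stiff
    method-of-lines integrator. Includes the fixed-point solution of the
    non-linear integral equation for the bound-CAM moment, aggregate
    detection diagnostics, deterministic fixture generators, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
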