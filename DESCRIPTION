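Package: cardalt
Title: Electromechanical Alternans in Human Ventricular Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: One-way excitation-contraction coupling pipeline for human
    ventricular myocytes: a stiff ionic ODE stage (membrane potential, twelve
    sarcolemmal currents, sarcoplasmic-reticulum calcium handling, three
    transmural cell variants with a steep-restitution parameterization) whose
    cytosolic calcium transient drives a cross-bridge myofilament mechanics
    stage (regulatory-unit activation, pre/post-rotation cross-bridge states,
    normalized active force, contractile ATP consumption, sarcomere-length
    dynamics under isotonic and pseudo-isometric loads). Includes basic-cycle-
    length sweep orchestration, per-beat metrics (APD, calcium transient,
    tension, equivalent cell length, ATP rate), alternans detection with onset
    refinement, restitution and tension-amplitude curves, and a parametric
    calcium-transient generator for testing the mechanics stage in isolation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
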