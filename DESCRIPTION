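Package: acwave
Title: Lie Symmetries and Solitary-Wave Solutions of the Bistable
    Allen-Cahn Biofilm Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Symbolic and numerical toolkit for the bistable Allen-Cahn
    reaction-diffusion equation used to model microbial biofilm density on
    a surface.  Computes the Lie point symmetry algebra of the equation
    (second prolongation, determining equations, generator basis and
    commutator table) with an exact rational polynomial engine, performs
    similarity and plane travelling-wave reductions, derives solitary-wave
    solutions by three expansion methods (generalized auxiliary equation,
    modified (G'/G^2) expansion and extended modified tanh expansion),
    audits published parameter sets by back-substitution, classifies the
    resulting wave profiles (kink, anti-kink, bright, dark, periodic,
    singular), and cross-checks front propagation with a finite-difference
    simulation of the one-dimensional reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
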