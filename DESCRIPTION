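Package: mcevertex
Title: Vertex-Model Simulation of Mechanical Cell Elimination in Growing Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional vertex dynamics model of a growing epithelial
    sheet in which crowding-induced (mechanical) cell elimination emerges from
    cell divisions, T1 rearrangements and T2 extrusions. Provides per-cell
    discrete Cauchy stress tensors, elimination-rate and fitness metrics,
    stress-dependent feedback laws (cell-cycle gating, fluidity regulation,
    stress-aligned division), heritable mechanical traits with an inheritance
    probability, and a mean-field ordinary-differential-equation approximation
    of trait-frequency competition dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    deSolve,
    minpack.lm,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
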