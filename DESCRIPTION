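Package: mcreservoir
Title: Multicellular Reservoir Computing with Diffusible Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a three-dimensional community of cells, each running a
    random Boolean network, communicating through diffusible signalling
    molecules whose concentrations are obtained from the steady state of a
    screened diffusion equation on a voxel grid. A binary input signal is
    emitted from one domain wall (Dirichlet boundary) and the community acts
    as a reservoir computer: a lasso-regularised linear readout trained on
    reservoir gene states approximates temporal Boolean functions such as the
    windowed median and parity. Includes the steady-state solver with
    input-threshold calibration, task generators (median, parity, arbitrary
    and recursive truth tables), Latin hypercube sampling with partial rank
    correlation (PRCC) sensitivity analysis, and experiment recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    glmnet,
    lhs,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
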