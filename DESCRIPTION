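Package: aquaflux
Title: Stopped-Flow Osmotic Permeability Analysis and Aquaporin Conformer
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and inverse analysis of stopped-flow osmotic
    volume traces for water and glycerol membrane permeability assays in
    erythrocytes and yeast. Provides a mechanistic two-flux cell-volume ODE
    model, single-exponential rate-constant extraction with fluorophore
    bleach correction, conversion of rate constants to permeability
    coefficients (Pf, Pgly), percent-inhibition and fold-change statistics,
    and Hill-model IC50 estimation with profile and bootstrap confidence
    intervals. Also post-processes molecular-dynamics collective-variable
    samples into two-dimensional free-energy landscapes with basin
    detection, threshold-based selection of binding-ready aquaporin
    conformers, and per-residue ligand contact profiling from multi-model
    PDB files. A seeded synthetic-data generator emulates every input so
    the full pipeline can be exercised and validated closed-loop.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    deSolve,
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
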