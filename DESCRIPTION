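Package: cellmatch
Title: Equilibrium and Dynamic Simulation of Cell Matching at a 1D Tissue Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the alignment (matching) of two facing rows of cells at a
    one-dimensional tissue-tissue interface, as in the contralateral cardioblast
    rows of the embryonic Drosophila heart. Provides an equilibrium Metropolis
    Monte-Carlo model in which type-specific adhesion energies compete with cell
    compressibility at an effective temperature, an overdamped dynamic vertex
    model with interfacial tensions and logarithmic elastic forces, the
    cell-mismatch metric and its spatial profiles, the gamma order parameter
    combining differential adhesion and compressibility, and an experiment layer
    (system-size scaling, gamma sweeps and collapse, effective-temperature
    sweeps, genotype-to-gamma mapping and inference, pattern-defect studies,
    stiffness sweeps) for ensemble studies of cell matching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
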