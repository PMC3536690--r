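Package: comfar
Title: Comparative Molecular Field Analysis (CoMFA) 3D-QSAR in R
Version: 0.1.0
Authors@R:
    person("comfar", "developers", email = "comfar@example.org", role = c("aut", "cre"))
Description: An open, tested re-implementation of the classic CoMFA 3D-QSAR
    workflow for congeneric small-molecule series: seeded 3D embedding,
    Gasteiger partial charges, rigid core-based least-squares alignment onto a
    reference compound, Lennard-Jones steric and Coulomb electrostatic probe
    fields sampled on a regular lattice, NIPALS partial least squares with
    leave-one-out cross-validation (PRESS, q2, SDEP), external test-set
    prediction, and coefficient-by-standard-deviation contour maps. Ships a
    curated 46-compound cytotoxic 3,5-diaryl-4,5-dihydropyrazole dataset with
    full characterization cross-checks, plus a synthetic-data module providing
    ground-truth recovery tests for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with rdkit, used as a subprocess for 3D
    conformer embedding only.
Config/testthat/edition: 3
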