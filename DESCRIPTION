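Package: cypsom
Title: Site-of-Metabolism Modelling of Heterotropic Drug-Drug Interactions
    at CYP3A4
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heterotropic cooperativity of cytochrome
    P450 CYP3A4 with midazolam as the probe substrate.  Implements a
    rapid-equilibrium two-site (productive + peripheral allosteric)
    occupancy model that predicts 1-hydroxy and 4-hydroxy midazolam
    formation rates and the site-of-metabolism (SOM) ratio as a function
    of substrate and effector concentration, with weighted nonlinear
    least-squares fitting, Langmuir spin-shift titration analysis and
    classification of effector mode (competitive versus allosteric).
    A companion geometric module classifies molecular-dynamics trajectory
    frames as productive/selective from distances between the substrate
    carbons and a virtual Compound I ferryl oxygen, and compares
    per-residue ligand contact frequencies between conditions.  Seeded
    synthetic-data generators for kinetic datasets, titration curves and
    toy coordinate trajectories make the whole pipeline testable without
    experimental or simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
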