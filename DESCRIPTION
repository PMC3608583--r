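Package: pmhcdyn
Title: Post-Simulation Analysis of Peptide-MHC Class II Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of
    peptide-MHC class II complexes: binding-site RMSD statistics after
    optimal superposition, four-compartment binding-groove width
    dissection, persistence-based hydrogen-bond, aromatic-stacking and
    water-excluded hydrophobic interaction networks, quasi-harmonic
    configurational entropy, solvated interaction energy (SIE) binding
    free energies with virtual alanine scanning, and conversion between
    binding free energy and IC50. Includes a synthetic-trajectory
    generator that plants known geometric and statistical structure so
    every analysis stage can be validated without running molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
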