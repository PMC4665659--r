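Package: hadp
Title: Temperature-Dependent Anisotropic Hydrogen Displacement Parameters by
    Segmented Rigid-Body (TLS+ARG) Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates anisotropic displacement parameters (ADPs) for hydrogen
    atoms in molecular crystal structures by combining external (lattice)
    motion, fitted as a segmented rigid body (TLS tensors plus attached rigid
    groups, each librating about a torsion axis) against the refined non-H
    ADPs, with internal (intramolecular) motion computed from harmonic normal
    modes via the quantum-oscillator coth law. Includes automatic rigid-body
    segmentation driven by a Hirshfeld rigid-bond rigidity index, readers and
    writers for CIF, SHELX .res and PDB structures, an environment-keyed cache
    of internal ADPs, the Gaussian-overlap ADP similarity statistic S, an
    inter-model ADP scaling fit, and a synthetic-data generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
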