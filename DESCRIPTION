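Package: chaoscalc
Title: Mechanical End-State Free Energies and the CHAOS Parameter for
    Lipid Packing Defect Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies lipid-packing-defect sensing by membrane-bound
    amphipathic peptides from reduced molecular-dynamics output. Converts
    diagonal pressure-tensor time series from constant-area bilayer runs
    into block-averaged surface tensions, evaluates the mechanical
    (end-state) stretching work and the relative binding free energy
    between stretched and tensionless membranes, and computes the
    end-state-invariant characteristic area of sensing (CHAOS). Includes
    thermodynamic-integration numerics with a Welch's-t cycle-closure
    check against the mechanical route, strain/curvature/vesicle-size
    geometry mappings for buckled membranes, a cycle-consistent synthetic
    data generator built on a Hookean membrane + peptide model, and a
    genetic-algorithm driver for directed evolution of peptide sequences
    with a pluggable fitness function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
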