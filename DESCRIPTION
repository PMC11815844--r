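Package: cppkit
Title: Steered-Pulling Free-Energy Estimation and Membrane Disruption
    Metrics for Cell-Penetrating Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of staged steered-pulling simulations of
    peptide-membrane crossing. Provides a one-dimensional overdamped
    Langevin pulling simulator with known ground-truth potentials, staged
    Jarzynski free-energy (potential of mean force) estimation with
    representative-replica hand-off, forward/backward hysteresis
    calibration, and bilayer disruption metrics computed from labelled
    coarse trajectories: acyl-chain order parameter, water-defined pore
    bottleneck radius, membrane thickness, area per lipid, residue-lipid
    contact occupancy and a four-way peptide-fate classification.
    Includes sequence-level peptide descriptors (Kyte-Doolittle
    hydropathy, formal net charge), a synthetic bilayer trajectory
    generator, and readers/writers for multi-model PDB, GRO, FASTA, CSV
    work logs and YAML run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
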