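Package: hvblock
Title: Equilibrium and Kinetic Analysis of Gating-Modifier Peptide Block
    of Dimeric Proton Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pharmacology of peptide-toxin block of the
    dimeric voltage-gated proton channel: Hill dose-response fits with
    optional partial maximal block, Boltzmann conductance-voltage fits,
    single-exponential wash-in/wash-out kinetics with bimolecular rate
    extraction, single-dose mutational energetics and thermodynamic
    double-mutant-cycle coupling, and mole-fraction membrane-partition
    analysis from liposome depletion assays.  A seeded synthetic-data
    layer generates every experiment class from a state-dependent
    two-site binding model so the full pipeline is testable without
    recordings, and a reporting layer assembles per-condition summaries
    and fold-change comparisons from CSV/JSON inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    withr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
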