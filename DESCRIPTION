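Package: helixread
Title: Helical Histone H3 Tail Readout by PHD Fingers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the structural and biophysical readout of
    the helical histone H3 N-terminal tail by PHD finger reader domains.
    Provides DSSP-style backbone hydrogen-bond detection and per-residue
    helicity profiling of peptide conformer ensembles, classification of
    bound H3 conformations (helical, bent, extended), an alignment census of
    the conserved acidic-wall Asp/Glu versus the methyl-K4 reader
    tryptophan, weighted NMR chemical-shift-perturbation analysis including
    the minimal-shift procedure, single-site isothermal titration
    calorimetry simulation and fitting with propagated binding
    thermodynamics, helix-propensity ranking of peptide variants, and seeded
    synthetic-data generators so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
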