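Package: chanalyze
Title: Binding-Pocket Geometry and Gating Analysis for Potassium-Channel
    Activator Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to localize and explain small-molecule activator action on
    tetrameric voltage-gated potassium channels (KCNQ1 and relatives).
    Reads atomic structures (PDB/mmCIF) as tidy atom tables and provides
    ligand-pocket delineation at a distance cutoff, residue-numbering maps
    across species and isoforms, anchored least-squares superposition with
    per-residue displacement maps, chi1 rotamer clash scanning against a
    van der Waals criterion, and pore-radius profiling along the symmetry
    axis. A voltage-dependent Markov gating simulator generates synthetic
    whole-cell and single-channel currents with fast inactivation (hooked
    tail currents) and an activator modifier, and the electrophysiology
    module implements tail-current back-extrapolation to a non-inactivated
    fraction, conductance-voltage Boltzmann fits, fold-change and Spearman
    rank statistics, and all-points amplitude histograms with Gaussian
    mixture fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
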