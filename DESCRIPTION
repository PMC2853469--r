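Package: srspot
Title: Residue-Level Statistical Potentials with a Shuffled Reference State
Version: 0.1.0
Authors@R:
    person("srspot", "maintainers", email = "srspot@example.org", role = c("aut", "cre"))
Description: Derivation and evaluation of residue-level, orientation-dependent
    knowledge-based statistical potentials for protein model quality assessment.
    Chains are reduced to C-beta interaction centers (virtual for glycine),
    ordered residue pairs are binned by C-beta distance and classified into
    three side-chain orientation classes, and energies are obtained by
    Boltzmann inversion against either a classic all-type-average reference or
    a Shuffled Reference State (label permutation within each chain, exact or
    Monte Carlo). Includes Sippl sparse-count smoothing, training-set selection
    filters for X-ray chains, GDT_TS-binned decoy ranking with the
    native-present rank-2 rule, paired one-tailed Wilcoxon comparison of
    scoring functions, a synthetic-data module with known ground-truth pair
    energies, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
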