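Package: dhipea
Title: Double-Hybrid Vertical Ionization Potentials and Electron Affinities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes vertical ionization potentials (VIPs) and vertical
    electron affinities (VEAs) for closed-shell molecules at double-hybrid
    density functional levels. Two correlated ansaetze are provided on top of
    a pluggable self-consistent-field reference: a perturbative CIS(D)-type
    second-order correction added a posteriori to the orbital-energy
    (Koopmans) value, and an iterative non-Dyson ADC(2)-type treatment solved
    as a folded nonlinear eigenvalue problem with a root-following Davidson
    algorithm. Second-order terms support global and spin-component
    (opposite-/same-spin) scaling. Two-electron integrals enter exclusively
    through a density-fitting (resolution-of-identity) factorization built
    block-selectively, so ionization calculations never touch the
    unoccupied-unoccupied integral block. A fixture module generates seeded
    synthetic reference states and dense spin-orbital brute-force oracles so
    every stage is testable without an external quantum chemistry program.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
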