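Package: thzbind
Title: Oscillating-Field Molecular Dynamics, THz Absorption Spectra, and
    Binding Free-Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale molecular dynamics and analysis pipeline for studying
    how an oscillating terahertz-band electric field modulates receptor-ligand
    binding. Provides a velocity-Verlet engine with Langevin thermostatting and
    a classical field coupling E(t) = A u cos(2 pi nu t + phi) acting on atomic
    partial charges; group-resolved absorption spectra from the Fourier
    transform of the charge-current autocorrelation function; geometric
    hydrogen-bond and hydrophobic-contact analysis with occupancy statistics
    and field-on versus field-off network differencing; and an MM-PBSA-style
    binding free-energy decomposition (molecular-mechanics terms, a
    finite-difference Poisson-Boltzmann polar solvation solver, and
    Shrake-Rupley surface-area nonpolar solvation) with per-residue attribution
    and bootstrap uncertainties. Synthetic generators build charged harmonic
    probes, host-guest pocket toys with known ground truth, and analytic test
    signals so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
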