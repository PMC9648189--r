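Package: dispersolv
Title: Solute-Solvent Dispersion Contributions to Solvation Free Energies
    and Solvatochromic Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the London dispersion contribution to the solvation
    free energy and to vertical electronic excitation energies within a
    polarizable continuum model of the solvent.  The solute is represented
    by an explicit electronic density whose damped electric-field
    fluctuations S2(r) are measured by Metropolis Monte Carlo sampling (or
    by deterministic quadrature for analytic model densities), integrated
    over the region outside a molecule-shaped cavity of interlocking
    atomic spheres, and multiplied by an excited-state-aware
    Casimir-Polder prefactor built from the solvent refractive index and
    ionization potential.  Includes the auxiliary-frequency construction
    that extends the ground-state theory to excited solutes, solvent
    dispersion data for six common solvents, cavity construction and
    scaling rules, exterior quadrature, and brute-force perturbation
    theory oracles (sum-over-states dispersion, Casimir-Polder
    integration, London and modified C6 coefficients) used to validate
    the closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
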