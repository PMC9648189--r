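# Shared fixtures: the frozen synthetic study conditions and light-weight
# quadrature settings for pipeline tests.

# Synthetic two-state solute in cyclohexane: one-electron Gaussian pair
# (ground sd 1 bohr, excited 1.4x more diffuse), carbonyl-like state data
# (I_gs = 0.36, I_exc = 0.19 Hartree, vertical transition 4.4 eV, b = 1.6),
# single carbon-centered cavity sphere.  Omega = 6 eV sits inside the
# admissible interval (4.4, 7.44) eV.
fixture_system <- function() {
  fix <- make_two_state_fixture(1.4)
  shift_system(
    fix$ground, fix$excited,
    electronic_state("ground", 0.36, 0, b = 1.6),
    electronic_state("excited", 0.19, 4.4, b = 1.6),
    list(atom("C", c(0, 0, 0))),
    solvent_model("cyclohexane")
  )
}

fixture_omega <- 6.0

# Light exterior/oracle quadrature orders for tests that only need ~1e-4
# relative accuracy (verified against order doubling in test-cavity).
quad_light <- list(radial_order = 16L, angular_order = 10L,
                   n_r = 40L, n_t = 30L)

hcho_atoms <- function() {
  list(atom("C", c(0, 0, 0)), atom("O", c(0, 0, 2.28)),
       atom("H", c(1.78, 0, -1.1)), atom("H", c(-1.78, 0, -1.1)))
}

# Independent transcription of the damping factor used to cross-check the
# packaged implementation.
f2_reference <- function(x) 1 - exp(-x) * (1 + x + x^2 / 2)

# Standard error of a sampler mean from independent-walker block means.
walker_se <- function(values, walker) {
  means <- tapply(values, walker, mean)
  stats::sd(means) / sqrt(length(means))
}
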