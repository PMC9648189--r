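# Solvent model: refractive-index dispersion, Clausius--Mossotti response,
# Omega validation and the Gamma prefactor.

test_that("refractive index evaluates the dispersion polynomial", {
  tab <- load_solvents()
  expect_setequal(tab$name, c("water", "ethanol", "cyclohexane",
                              "chloroform", "carbon tetrachloride",
                              "toluene"))
  w <- solvent_model("water")
  expect_identical(refractive_index(w, 0), 1.32315)
  expect_equal(refractive_index(w, 4),
               1.32315 + 0.00201432 * 16 + 6.21176e-06 * 256,
               tolerance = 1e-12)
  expect_error(refractive_index(w, -1), ">= 0")
  # strictly increasing on [0, 8] eV for every packaged solvent
  om <- seq(0, 8, by = 0.25)
  for (nm in tab$name) {
    eta <- suppressWarnings(refractive_index(solvent_model(nm), om))
    expect_true(all(diff(eta) > 0), label = nm)
  }
  # direct override for frequencies outside the fit's validity
  cy <- solvent_model("cyclohexane", eta_omega = 1.60)
  expect_equal(refractive_index(cy, 7.21), 1.60)
  expect_equal(refractive_index(cy, 0), cy$eta0)
})

test_that("Clausius-Mossotti factor has the right limits", {
  expect_equal(clausius_mossotti(1), 0)
  expect_gt(clausius_mossotti(1e6), 1 - 1e-10)
  eta <- 1.41142
  expect_equal(clausius_mossotti(eta), (eta^2 - 1) / (eta^2 + 2),
               tolerance = 1e-15)
  expect_error(clausius_mossotti(0.9), ">= 1")
})

test_that("Omega validation enforces the admissible interval", {
  cy <- solvent_model("cyclohexane")
  # pi->pi* acrolein-like state: transition 6.93 eV, onset 7.44 eV
  pipi <- electronic_state("excited", 0.23, 6.93, b = 1.6)
  ok <- validate_omega(7.21, pipi, cy)
  expect_s3_class(ok, "omega_choice")
  expect_equal(ok$valid_interval, c(6.93, 7.44))

  gs <- solute_state("acetone", "ground")
  expect_equal(validate_omega(0, gs, cy)$omega, 0)
  expect_error(validate_omega(1, gs, cy), "Omega = 0")

  exc <- solute_state("acetone", "n-pi*")
  expect_error(validate_omega(0, exc, cy), "4.69.*7.44")
  expect_error(validate_omega(7.6, exc, cy), "4.69.*7.44")
  # missing onset must be supplied by the user
  w <- solvent_model("water")
  expect_error(validate_omega(6, exc, w), "absorption onset")
  w2 <- solvent_model("water", first_absorption = 7.0)
  expect_equal(validate_omega(6, exc, w2)$omega, 6)
})

test_that("Gamma(0) reduces exactly to the ground-state prefactor", {
  tab <- load_solvents()
  for (nm in tab$name) {
    sv <- solvent_model(nm)
    for (solute in c("formaldehyde", "acrolein", "acetone")) {
      st <- solute_state(solute, "ground")
      g <- gamma_prefactor(st, sv, 0)
      ref <- 3 / (8 * pi) * clausius_mossotti(sv$eta0) *
        sv$ionization_potential /
        (st$ionization_potential + sv$ionization_potential)
      expect_equal(g$value, ref, tolerance = 1e-15)
      expect_gt(g$value, 0)
    }
  }
})

test_that("Gamma is continuous in Omega near zero", {
  sv <- solvent_model("cyclohexane")
  st0 <- electronic_state("ground", 0.36, 0, b = 1.6)
  st_eps <- electronic_state("excited", 0.36, 1e-6, b = 1.6)
  g0 <- gamma_prefactor(st0, sv, 0)
  g_eps <- gamma_prefactor(st_eps, sv, 1e-4)
  expect_equal(g_eps$value, g0$value, tolerance = 1e-5)
})

test_that("Gamma matches the Casimir-Polder quadrature oracle", {
  # synthetic solvent whose response is exactly one effective level at I_B:
  # then the Unsold closure behind the closed form is exact and the
  # adaptively integrated prefactor must agree to quadrature accuracy
  IA <- 0.19; IB <- 0.40
  om_eV <- 5; om <- convert_units(om_eV, "eV", "hartree")
  eta0 <- 1.35
  cm0 <- clausius_mossotti(eta0)
  cmW <- cm0 * IB^2 / (IB^2 - om^2)
  etaW <- sqrt((1 + 2 * cmW) / (1 - cmW))
  st <- electronic_state("excited", IA, 4.5, b = 1.6)
  sv <- solvent_model("synthetic-one-level", eta0 = eta0, A2 = 0, A4 = 0,
                      ionization_potential = IB, first_absorption = 6.5)
  g <- gamma_prefactor(st, sv, om_eV, eta_omega = etaW)
  orc <- gamma_quadrature_oracle(cm0, cmW, IA, om)
  expect_equal(orc$effective_level, IB, tolerance = 1e-12)
  expect_lt(abs(g$value - orc$value) / orc$value, 1e-6)
})

test_that("Gamma is linear in each Clausius-Mossotti factor", {
  sv <- solvent_model("cyclohexane")
  st <- electronic_state("excited", 0.19, 4.4, b = 1.6)
  g <- gamma_prefactor(st, sv, 6)
  cmp <- g$components
  om <- convert_units(6, "eV", "hartree")
  IB <- sv$ionization_potential
  ratio <- cmp$W_B / (cmp$W_A + cmp$W_B)
  expect_equal(g$value,
               3 / (8 * pi) * ratio *
                 (2 * cmp$cm_omega - cmp$cm0 * IB / (IB + om)),
               tolerance = 1e-14)
  # doubling the CM(Omega) factor adds exactly its own contribution
  g2 <- gamma_prefactor(st, sv, 6,
                        eta_omega = sqrt((1 + 4 * cmp$cm_omega) /
                                           (1 - 2 * cmp$cm_omega)))
  expect_equal(g2$value - g$value,
               3 / (8 * pi) * ratio * 2 * cmp$cm_omega,
               tolerance = 1e-12)
})

test_that("Gamma rejects nonpositive shifted closure parameters", {
  # an artificial solvent with onset above its ionization potential lets
  # Omega exceed I_B, which must be refused
  sv <- solvent_model("soft", eta0 = 1.4, A2 = 1e-3, A4 = 1e-6,
                      ionization_potential = 0.20, first_absorption = 8)
  st <- electronic_state("excited", 0.19, 4.4, b = 1.6)
  expect_error(gamma_prefactor(st, sv, 6), "W_B")
})

test_that("Gamma stays positive and smooth across the valid Omega window", {
  sv <- solvent_model("cyclohexane")
  st <- electronic_state("excited", 0.19, 4.4, b = 1.6)
  om <- seq(4.5, 7.3, by = 0.2)
  vals <- vapply(om, function(w) gamma_prefactor(st, sv, w)$value,
                 numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(abs(diff(vals)) < 0.1 * max(abs(vals))))
})
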