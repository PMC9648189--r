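# Model systems: sampler correctness against analytic moments, the synthetic
# two-state pair, and the escape-fraction estimator for b.

test_that("atoms validate their fields and XYZ files round-trip units", {
  expect_error(atom("C", c(0, 0)), "3-vector")
  expect_error(atom("Xx", c(0, 0, 0)), "unknown element")
  expect_error(atom("C", c(0, 0, 0), nuclear_charge = -1), "> 0")

  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "formaldehyde fragment, bohr",
               "C 0 0 0", "O 0 0 2.28"), path)
  ats <- read_xyz(path)
  expect_equal(ats[[2]]$position, c(0, 0, 2.28))

  writeLines(c("1", "angstrom default", "C 0 0 1.0"), path)
  ats2 <- read_xyz(path)
  expect_equal(ats2[[1]]$position[3], 1 / 0.529177210903, tolerance = 1e-10)
})

test_that("packaged analytic densities are normalized (radial quadrature)", {
  for (wf in list(gaussian_wavefunction(1.3), hydrogenic_wavefunction(1.7))) {
    marg <- wf$marginals[[1]]
    dens <- function(r) {
      X <- cbind(marg$center[1] + r, marg$center[2], marg$center[3])
      exp(dispersolv:::.marginal_log_density(marg, X))
    }
    norm <- stats::integrate(function(r) 4 * pi * r^2 * dens(r), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-8)
    # closed-form tail used by estimate_b agrees with direct quadrature
    for (a in c(0.5, 1.5, 3)) {
      tail_quad <- stats::integrate(function(r) 4 * pi * r^2 * dens(r), a,
                                    Inf, rel.tol = 1e-10)$value
      expect_equal(dispersolv:::.marginal_tail(marg, a), tail_quad,
                   tolerance = 1e-8)
    }
  }
})

test_that("Metropolis sampling reproduces analytic moments", {
  wf <- gaussian_wavefunction(sd = 1)
  smp <- sample_configurations(wf, 5e4, seed = 11, step_size = 1.2,
                               n_walkers = 200L)
  expect_gt(smp$acceptance_rate, 0)
  expect_lt(smp$acceptance_rate, 1)
  for (ax in 1:3) {
    x <- smp$snapshots[, 1, ax]
    v <- mean(x^2) - mean(x)^2
    se <- walker_se((x - mean(x))^2, smp$walker)
    expect_lt(abs(v - 1), 3 * se)
  }

  Z <- 1.4
  wh <- hydrogenic_wavefunction(Z = Z)
  sh <- sample_configurations(wh, 1e5, seed = 23, step_size = 1 / Z,
                              n_walkers = 250L)
  r <- sqrt(rowSums(sh$snapshots[, 1, ]^2))
  expect_lt(abs(mean(r) - 1.5 / Z), 3 * walker_se(r, sh$walker))
})

test_that("sampling is deterministic for a fixed seed", {
  wf <- hydrogenic_wavefunction()
  a <- sample_configurations(wf, 500, seed = 99, step_size = 1)
  b <- sample_configurations(wf, 500, seed = 99, step_size = 1)
  expect_identical(a$snapshots, b$snapshots)
  c <- sample_configurations(wf, 500, seed = 100, step_size = 1)
  expect_false(identical(a$snapshots, c$snapshots))
})

test_that("sampler rejects degenerate inputs", {
  wf <- gaussian_wavefunction()
  expect_error(sample_configurations(wf, 0, seed = 1), ">= 1")
  expect_error(sample_configurations(wf, 10, seed = 1, step_size = 0), "> 0")
  diverging <- model_wavefunction(1L, log_density = function(X)
    rowSums(X^2), center_of_charge = c(0, 0, 0))
  expect_error(sample_configurations(diverging, 100, seed = 1,
                                     step_size = 5, burn_in = 200))
})

test_that("two-state fixture scales second moments and stays normalized", {
  expect_error(make_two_state_fixture(1), "> 1")
  expect_error(make_two_state_fixture(0.5), "> 1")

  fix <- make_two_state_fixture(2)
  m_g <- dispersolv:::.marginal_second_moment(fix$ground$marginals[[1]])
  m_e <- dispersolv:::.marginal_second_moment(fix$excited$marginals[[1]])
  expect_equal(m_e / m_g, 4, tolerance = 1e-12)
  expect_identical(fix$ground$n_electrons, fix$excited$n_electrons)

  near <- make_two_state_fixture(1 + 1e-9)
  m_n <- dispersolv:::.marginal_second_moment(near$excited$marginals[[1]])
  expect_equal(m_n / m_g * 4, 4, tolerance = 1e-6)

  # more diffuse state has larger field fluctuations at an exterior point
  dmp <- damping_spec(1.6)
  p <- c(0, 0, 7)
  expect_gt(s2_oracle(fix$excited, p, dmp), s2_oracle(fix$ground, p, dmp))
})

test_that("escape-fraction radius hits its target and maps to b", {
  wf <- gaussian_wavefunction(sd = 1)
  est <- estimate_b(wf, list(atom("C", c(0, 0, 0))))
  expect_equal(est$escape_fraction, 0.5, tolerance = 1e-6)
  # independent check of the escape fraction by direct radial quadrature
  tail_quad <- stats::integrate(function(r)
    4 * pi * r^2 * (2 * pi)^(-1.5) * exp(-r^2 / 2), est$radius, Inf,
    rel.tol = 1e-10)$value
  expect_equal(tail_quad, 0.5, tolerance = 1e-5)
  expect_equal(est$b, dispersolv:::.f2_half_point() / est$radius,
               tolerance = 1e-12)
  # override of the radius -> b map
  est2 <- estimate_b(wf, list(atom("C", c(0, 0, 0))),
                     b_map = function(R) 2 / R)
  expect_equal(est2$b, 2 / est$radius, tolerance = 1e-9)
})

test_that("coincident sphere centers reduce to the single-center case", {
  wf <- gaussian_wavefunction(sd = 1)
  one <- estimate_b(wf, list(atom("C", c(0, 0, 0))))
  two <- estimate_b(wf, list(atom("C", c(0, 0, 0)), atom("C", c(0, 0, 0))))
  expect_equal(two$radius, one$radius, tolerance = 1e-9)
  expect_equal(two$effective_spheres, 1)
})

test_that("well-separated centers carry an escape target of 0.5 each", {
  wf2 <- product_wavefunction(list(
    dispersolv:::.marginal("gaussian", c(0, 0, -12), sd = 1),
    dispersolv:::.marginal("gaussian", c(0, 0, 12), sd = 1)))
  est <- estimate_b(wf2, list(atom("C", c(0, 0, -12)),
                              atom("C", c(0, 0, 12))))
  expect_equal(est$target, 1.0, tolerance = 1e-9)
  expect_equal(est$escape_fraction, 1.0, tolerance = 1e-6)
  # brute-force escape fraction: direct sampling of the two independent
  # marginals, counting electrons outside the union of spheres
  withr::with_seed(5, {
    n <- 2e5
    esc <- 0
    for (ctr in list(c(0, 0, -12), c(0, 0, 12))) {
      x <- matrix(rnorm(3 * n), n, 3) +
        matrix(ctr, n, 3, byrow = TRUE)
      d1 <- sqrt(rowSums(sweep(x, 2, c(0, 0, -12))^2))
      d2 <- sqrt(rowSums(sweep(x, 2, c(0, 0, 12))^2))
      esc <- esc + mean(d1 > est$radius & d2 > est$radius)
    }
    expect_lt(abs(esc - 1.0), 3 * sqrt(2 * 0.25 / n) + 0.01)
  })
})

test_that("escape fraction decreases strictly with radius", {
  wf <- gaussian_wavefunction(sd = 1)
  ctr <- matrix(0, 1, 3)
  radii <- seq(0.5, 3, by = 0.5)
  esc <- vapply(radii, function(R)
    dispersolv:::.escape_fraction(wf, ctr, R), numeric(1))
  expect_true(all(diff(esc) < 0))
})

test_that("estimate_b rejects unattainable targets and missing centers", {
  wf <- gaussian_wavefunction(sd = 1)
  expect_error(estimate_b(wf, list()), "at least one")
  # one electron cannot escape 0.5 electrons from each of two disjoint spheres
  expect_error(
    estimate_b(wf, list(atom("C", c(0, 0, -40)), atom("C", c(0, 0, 40)))),
    "unattainable")
})
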