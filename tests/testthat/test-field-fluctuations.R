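# Damped fields, directional variances and the S^2 quadrature oracle.

test_that("damping factor regularizes the field and vanishes correctly", {
  expect_error(damping_spec(0), "> 0")
  expect_error(damping_spec(-1), "> 0")
  x <- c(1e-6, 1e-3, 0.05, 0.5, 2, 10, 50)
  f <- f2_damping(x)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) > 0))
  # agrees with an independent transcription of the closed form
  expect_equal(f[x >= 0.05], f2_reference(x[x >= 0.05]), tolerance = 1e-12)
  # small-x series limit x^3/6
  expect_equal(f2_damping(1e-4), 1e-12 / 6, tolerance = 1e-3)
})

test_that("damped field has the right limits", {
  dmp <- damping_spec(2)
  # long range: undamped Coulomb field 1/r^2
  E <- damped_field(c(0, 0, 0), c(0, 0, 30), dmp)
  expect_equal(E, c(0, 0, 1 / 900), tolerance = 1e-8)
  # electron coincident with the probe: finite (zero) field
  expect_equal(damped_field(c(1, 2, 3), c(1, 2, 3), dmp), c(0, 0, 0))
  # generic distance: undamped field times the independent damping factor
  r <- 1.7
  E2 <- damped_field(c(0, 0, 0), c(0, 0, r), dmp)
  expect_equal(E2[3], f2_reference(2 * r) / r^2, tolerance = 1e-12)
})

test_that("field variance handles degenerate and rotated inputs", {
  wf <- gaussian_wavefunction()
  dmp <- damping_spec(1.6)
  smp <- sample_configurations(wf, 200, seed = 3, step_size = 1.2)

  frozen <- smp
  frozen$snapshots[] <- 0.3   # all snapshots identical
  fv0 <- field_variance(frozen, c(0, 0, 5), c(0, 0, 0), dmp)
  expect_equal(fv0$sigma2, c(L = 0, T1 = 0, T2 = 0), tolerance = 1e-28)
  expect_equal(fv0$s2, 0, tolerance = 1e-28)

  one <- smp
  one$snapshots <- one$snapshots[1, , , drop = FALSE]
  one$n_kept <- 1L
  expect_error(field_variance(one, c(0, 0, 5), c(0, 0, 0), dmp),
               "at least 2")

  # the transverse pair is trace-invariant: S^2 equals the raw component
  # variance sum regardless of the triad orientation
  fv <- field_variance(smp, c(1, 2, 5), c(0, 0, 0), dmp)
  E <- dispersolv:::.field_batch(smp$snapshots, c(1, 2, 5), dmp$b)
  raw <- sum(apply(E, 2, function(v) mean(v^2) - mean(v)^2))
  expect_equal(fv$s2, raw, tolerance = 1e-12)
  expect_true(all(abs(tcrossprod(fv$axes) - diag(3)) < 1e-12))
})

test_that("oracle S^2 obeys symmetry, decay and degenerate limits", {
  dmp <- damping_spec(1.6)
  # point density: no fluctuation
  pointwf <- model_wavefunction(1L, marginals = list(
    dispersolv:::.marginal("point", c(0, 0, 0))))
  expect_equal(s2_oracle(pointwf, c(0, 0, 4), dmp), 0)

  wf <- gaussian_wavefunction(1)
  # far-field log-log slope is -6 (fluctuating-dipole field variance)
  rr <- c(15, 30, 60, 150)
  vv <- vapply(rr, function(d) s2_oracle(wf, c(0, 0, d), dmp), numeric(1))
  slopes <- diff(log(vv)) / diff(log(rr))
  expect_true(all(abs(slopes + 6) < 0.05))

  # mirror symmetry of a symmetric density
  expect_equal(s2_oracle(wf, c(0, 0, 6), dmp),
               s2_oracle(wf, c(0, 0, -6), dmp), tolerance = 1e-10)
  # off-axis probes: S^2 depends only on distance for an isotropic density
  expect_equal(s2_oracle(wf, c(6, 0, 0), dmp),
               s2_oracle(wf, c(0, 0, 6), dmp), tolerance = 1e-10)

  # directional variances on a symmetry axis: transverse pair degenerate
  pr <- s2_oracle(wf, c(0, 0, 6), dmp, components = TRUE)
  expect_equal(pr$sigma2[["T1"]], pr$sigma2[["T2"]], tolerance = 1e-12)
  expect_equal(sum(pr$sigma2), pr$s2, tolerance = 1e-14)
  # mean field is purely longitudinal there
  expect_equal(pr$mean_field[1:2], c(0, 0), tolerance = 1e-14)
})

test_that("oracle quadrature is converged and rotation invariant", {
  dmp <- damping_spec(1.6)
  wf <- gaussian_wavefunction(1)
  a <- s2_oracle(wf, c(0, 0, 5), dmp, n_r = 80, n_t = 60)
  b <- s2_oracle(wf, c(0, 0, 5), dmp, n_r = 160, n_t = 120)
  expect_lt(abs(a - b) / b, 1e-6)

  wh <- hydrogenic_wavefunction(1.2, center = c(0.5, -0.3, 0.2))
  a2 <- s2_oracle(wh, c(4, 1, -2), dmp)                 # default orders
  b2 <- s2_oracle(wh, c(4, 1, -2), dmp, n_r = 240, n_t = 160)
  expect_lt(abs(a2 - b2) / b2, 1e-6)

  # rigid rotation applied to density center and probe leaves S^2 unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- c(0.8, 0, 0); p <- c(5, 1, 2)
  wf1 <- gaussian_wavefunction(1, center = ctr)
  wf2 <- gaussian_wavefunction(1, center = as.numeric(Rz %*% ctr))
  expect_equal(s2_oracle(wf1, p, dmp),
               s2_oracle(wf2, as.numeric(Rz %*% p), dmp), tolerance = 1e-9)
})

test_that("Monte Carlo S^2 converges to the oracle", {
  dmp <- damping_spec(1.6)
  wf <- gaussian_wavefunction(1)
  smp <- sample_configurations(wf, 3e4, seed = 17, step_size = 1.2,
                               n_walkers = 150L)
  for (p in list(c(0, 0, 5), c(4, 0, 3))) {
    fv <- field_variance(smp, p, wf$center_of_charge, dmp)
    expect_lt(abs(fv$s2 - s2_oracle(wf, p, dmp)), 3 * fv$mc_error)
  }
})

test_that("fluctuation grids share one sample and respect state ordering", {
  dmp <- damping_spec(1.6)
  fix <- make_two_state_fixture(1.4)
  expect_error(fluctuation_grid(fix$ground, matrix(0, 0, 3), dmp), "empty")

  # singleton MC grid equals field_variance
  smp <- sample_configurations(fix$ground, 2000, seed = 9, step_size = 1.2)
  g1 <- fluctuation_grid(fix$ground, matrix(c(0, 0, 6), 1), dmp,
                         sample = smp)
  fv <- field_variance(smp, c(0, 0, 6), fix$ground$center_of_charge, dmp)
  expect_equal(g1$s2, fv$s2, tolerance = 1e-12)

  # oracle grid over a plane: excited >= ground pointwise outside the bulk
  pts <- as.matrix(expand.grid(x = seq(5, 9, by = 2), y = 0,
                               z = seq(-8, 8, by = 4)))
  gg <- fluctuation_grid(fix$ground, pts, dmp)
  ge <- fluctuation_grid(fix$excited, pts, dmp)
  expect_true(all(ge$s2 >= gg$s2))
  expect_identical(attr(gg, "provenance"), "quadrature-oracle")

  # mirrored points give mirrored values
  gm <- fluctuation_grid(fix$ground, -pts, dmp)
  expect_equal(gm$s2, gg$s2, tolerance = 1e-10)

  # tabular export for plotting
  path <- withr::local_tempfile(fileext = ".dat")
  write_grid(gg, path)
  reread <- utils::read.table(path, header = TRUE)
  expect_equal(reread$s2, gg$s2, tolerance = 1e-6)
})
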