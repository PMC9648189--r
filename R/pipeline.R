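# Assembly of the dispersion solvation free energy, solvatochromic shifts,
# cavity-scaling curves and reference-anchored shift extraction.

#' Packaged solute-state data
#'
#' Damping parameters `b` (1/bohr), ionization potentials (Hartree) and
#' vacuum vertical transition energies (eV) for the three packaged carbonyl
#' solutes in their ground and n->pi* excited states.
#'
#' @return data frame with columns `solute`, `state`, `b`,
#'   `ionization_hartree`, `transition_eV`.
#' @export
load_solute_states <- function() {
  utils::read.delim(.extdata("solute_states.tsv"), stringsAsFactors = FALSE)
}

#' Look up a packaged electronic state
#'
#' @param solute one of the packaged solute names.
#' @param state `"ground"` or `"n-pi*"`.
#' @return an [electronic_state()].
#' @export
solute_state <- function(solute, state = c("ground", "n-pi*")) {
  state <- match.arg(state)
  tab <- load_solute_states()
  row <- tab[tab$solute == solute & tab$state == state, ]
  if (nrow(row) != 1L)
    stop("no packaged data for solute '", solute, "', state '", state, "'")
  electronic_state(if (state == "ground") "ground" else "excited",
                   ionization_potential = row$ionization_hartree,
                   vertical_transition_energy = row$transition_eV,
                   b = row$b)
}

# Per-block Monte Carlo S^2 values at many points: points x nblocks matrix.
.s2_mc_blocks <- function(sample, points, damping, nblocks = 16L) {
  n <- sample$n_kept
  nb <- max(2L, min(as.integer(nblocks), n %/% 2L))
  blk <- cut(seq_len(n), nb, labels = FALSE)
  P <- nrow(points)
  out <- matrix(NA_real_, P, nb)
  s2 <- numeric(P)
  for (j in seq_len(P)) {
    E <- .field_batch(sample$snapshots, points[j, ], damping$b)
    s2[j] <- sum(colMeans(E^2) - colMeans(E)^2)
    for (k in seq_len(nb)) {
      Eb <- E[blk == k, , drop = FALSE]
      out[j, k] <- sum(colMeans(Eb^2) - colMeans(Eb)^2)
    }
  }
  list(s2 = s2, blocks = out)
}

# Exterior integral of S^2 for one wavefunction/cavity pair.
.exterior_s2_integral <- function(wf, cavity, damping,
                                  method = "auto", sample = NULL,
                                  radial_order = 24L, angular_order = 12L,
                                  r_max = NULL, r_max_mult = 6,
                                  nblocks = 16L, n_r = 64L, n_t = 48L) {
  if (method == "auto")
    method <- if (!is.null(sample)) "mc"
      else if (wf$has_analytic_marginals) "oracle" else "mc"
  quad <- exterior_quadrature(cavity, radial_order, angular_order,
                              r_max = r_max, r_max_mult = r_max_mult)
  if (method == "oracle") {
    vals <- .s2_oracle_points(wf, quad$nodes, damping, n_r, n_t)
    tails <- .s2_oracle_points(wf, quad$tail_nodes, damping, n_r, n_t)
    res <- quadrature_integrate(quad, vals, tails)
    list(total = res$total, integral = res$integral, tail = res$tail,
         mc_error = 0, quad = quad, method = "oracle")
  } else {
    if (is.null(sample))
      stop("`sample` is required for the Monte Carlo path")
    vb <- .s2_mc_blocks(sample, quad$nodes, damping, nblocks)
    tb <- .s2_mc_blocks(sample, quad$tail_nodes, damping, nblocks)
    res <- quadrature_integrate(quad, vb$s2, tb$s2)
    nb <- ncol(vb$blocks)
    block_totals <- vapply(seq_len(nb), function(k)
      quadrature_integrate(quad, vb$blocks[, k], tb$blocks[, k])$total,
      numeric(1))
    list(total = res$total, integral = res$integral, tail = res$tail,
         mc_error = stats::sd(block_totals) / sqrt(nb), quad = quad,
         method = "mc")
  }
}

#' Dispersion contribution to the solvation free energy
#'
#' Computes `DeltaG_disp = -Gamma(Omega) * int_{outside cavity} S^2(r) d^3r`
#' (Hartree), with `S^2` evaluated either by the deterministic quadrature
#' oracle (analytic model densities) or from a Monte Carlo snapshot set, and
#' the exterior integral performed by [exterior_quadrature()] plus the
#' `1/r^6` tail correction.  Dispersion stabilizes: the result is `<= 0`
#' whenever `Gamma > 0`.
#'
#' @param wf a [model_wavefunction()] for the electronic state under study.
#' @param cavity a [build_cavity()] result (same solvent as `gamma`).
#' @param gamma a [gamma_prefactor()].
#' @param damping a [damping_spec()] (typically from the state's `b`).
#' @param method `"auto"`, `"oracle"` or `"mc"`.
#' @param sample optional [sample_configurations()] result for the Monte
#'   Carlo path.
#' @param radial_order,angular_order exterior-quadrature orders.
#' @param r_max,r_max_mult truncation radius control.
#' @param nblocks blocks for the Monte Carlo error estimate.
#' @param n_r,n_t oracle quadrature orders.
#' @param check_convergence if `TRUE`, repeat with doubled exterior orders
#'   and error out when the integral moves by more than `conv_tol`
#'   relatively.
#' @param conv_tol relative convergence tolerance for the doubling check.
#' @return object of class `"dispersion_result"` with `delta_g` (Hartree),
#'   `delta_g_eV`, `state_label`, `omega_eV`, `scale`, `integral` (a.u.),
#'   `tail`, `quadrature_error`, `mc_error` (both Hartree).
#' @export
dispersion_free_energy <- function(wf, cavity, gamma, damping,
                                   method = c("auto", "oracle", "mc"),
                                   sample = NULL,
                                   radial_order = 24L, angular_order = 12L,
                                   r_max = NULL, r_max_mult = 6,
                                   nblocks = 16L, n_r = 64L, n_t = 48L,
                                   check_convergence = FALSE,
                                   conv_tol = 0.005) {
  stopifnot(inherits(wf, "model_wavefunction"),
            inherits(cavity, "cavity"),
            inherits(gamma, "gamma_prefactor"),
            inherits(damping, "damping_spec"))
  method <- match.arg(method)
  if (!is.na(gamma$solvent_name) && gamma$solvent_name != cavity$solvent_name)
    stop("gamma prefactor (", gamma$solvent_name, ") and cavity (",
         cavity$solvent_name, ") refer to different solvents")
  res <- .exterior_s2_integral(wf, cavity, damping, method, sample,
                               radial_order, angular_order, r_max,
                               r_max_mult, nblocks, n_r, n_t)
  qerr <- NA_real_
  if (check_convergence) {
    res2 <- .exterior_s2_integral(wf, cavity, damping, res$method, sample,
                                  2L * radial_order, 2L * angular_order,
                                  r_max, r_max_mult, nblocks, n_r, n_t)
    qerr <- abs(gamma$value) * abs(res2$total - res$total)
    tol_abs <- conv_tol * abs(gamma$value * res$total) +
      3 * abs(gamma$value) * res$mc_error
    if (qerr > tol_abs && tol_abs > 0)
      stop("exterior quadrature not converged under order doubling")
  }
  dg <- -gamma$value * res$total
  structure(list(
    delta_g = dg,
    delta_g_eV = hartree_to_ev(dg),
    state_label = gamma$state_label,
    omega_eV = gamma$components$omega_eV,
    scale = cavity$scale,
    integral = res$total,
    tail = res$tail,
    quadrature_error = qerr,
    mc_error = abs(gamma$value) * res$mc_error,
    solvent_name = cavity$solvent_name,
    method = res$method
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "DeltaG_disp = %.6f Hartree (%.4f eV) [%s state, %s, scale %.3f, Omega %g eV]\n",
    x$delta_g, x$delta_g_eV, x$state_label, x$solvent_name, x$scale,
    x$omega_eV))
  if (x$mc_error > 0)
    cat(sprintf("  MC error %.2e Hartree (%s)\n", x$mc_error, x$method))
  invisible(x)
}

#' Dispersion solvatochromic shift
#'
#' Difference of the excited- and ground-state dispersion free energies
#' (excited minus ground); a negative value is a red shift.
#'
#' @param ground a [dispersion_free_energy()] result at `Omega = 0`.
#' @param excited a [dispersion_free_energy()] result at a validated Omega.
#' @return object of class `"shift_result"` with the shift in eV and cm^-1.
#' @export
solvatochromic_shift <- function(ground, excited) {
  stopifnot(inherits(ground, "dispersion_result"),
            inherits(excited, "dispersion_result"))
  if (ground$omega_eV != 0)
    stop("the ground-state result must be computed at Omega = 0")
  if (ground$solvent_name != excited$solvent_name)
    stop("ground and excited results refer to different solvents")
  if (abs(ground$scale - excited$scale) > 1e-12)
    stop("ground and excited results use different cavity scales")
  shift_eV <- excited$delta_g_eV - ground$delta_g_eV
  structure(list(
    shift_eV = shift_eV,
    shift_cm1 = convert_units(shift_eV, "eV", "cm-1"),
    ground = ground, excited = excited,
    omega_eV = excited$omega_eV,
    mc_error_eV = hartree_to_ev(sqrt(ground$mc_error^2 +
                                       excited$mc_error^2))
  ), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  kind <- if (x$shift_eV < 0) "red" else "blue"
  cat(sprintf(
    "Dispersion solvatochromic shift: %.4f eV (%.0f cm^-1, %s shift)\n",
    x$shift_eV, x$shift_cm1, kind))
  cat(sprintf("  Omega = %g eV; ground %.4f eV, excited %.4f eV\n",
              x$omega_eV, x$ground$delta_g_eV, x$excited$delta_g_eV))
  invisible(x)
}

#' Bundle a ground/excited system for shift calculations
#'
#' @param ground_wf,excited_wf [model_wavefunction()]s for the two states.
#' @param ground_state,excited_state [electronic_state()]s carrying `I`,
#'   transition energy and `b`.
#' @param atoms list of [atom()]s carrying the cavity sphere centers.
#' @param solvent a [solvent_model()].
#' @return object of class `"shift_system"`.
#' @export
shift_system <- function(ground_wf, excited_wf, ground_state, excited_state,
                         atoms, solvent) {
  stopifnot(inherits(ground_wf, "model_wavefunction"),
            inherits(excited_wf, "model_wavefunction"),
            inherits(ground_state, "electronic_state"),
            inherits(excited_state, "electronic_state"),
            inherits(solvent, "solvent_model"))
  if (ground_state$label != "ground" || excited_state$label != "excited")
    stop("state labels must be ground/excited")
  if (inherits(atoms, "atom")) atoms <- list(atoms)
  structure(list(ground_wf = ground_wf, excited_wf = excited_wf,
                 ground_state = ground_state, excited_state = excited_state,
                 atoms = atoms, solvent = solvent),
            class = "shift_system")
}

.system_dg <- function(system, factor, omega_eV, state, ...) {
  wf <- if (state == "ground") system$ground_wf else system$excited_wf
  st <- if (state == "ground") system$ground_state else system$excited_state
  cav <- build_cavity(system$atoms, system$solvent$name, scale = factor)
  gam <- gamma_prefactor(st, system$solvent, omega_eV)
  dispersion_free_energy(wf, cav, gam, damping_spec(st$b), ...)
}

#' Dispersion free energy versus cavity scaling factor
#'
#' Computes ground- and excited-state dispersion free energies over a grid of
#' cavity scale factors and a grid of Omega values.  The exterior integral of
#' `S^2` is computed once per (state, factor) and combined with each
#' `Gamma(Omega)`, so curves at different Omega share the same underlying
#' integral (and, on the Monte Carlo path, the same snapshot set via the
#' `samples` argument) and are not noise-dominated relative to each other.
#'
#' @param system a [shift_system()].
#' @param factors strictly increasing cavity scale factors.
#' @param omegas Omega values (eV) for the excited state, each validated.
#' @param samples optional list with elements `ground` and `excited`: shared
#'   [sample_configurations()] results for the Monte Carlo path.
#' @param ... passed to the exterior integration (orders, method, ...).
#' @return object of class `"scaling_curve"`: `factors`, `omegas`,
#'   `ground_eV` (vector), `excited_eV` (factors x omegas matrix),
#'   `ground_err_eV`, `excited_err_eV`, plus the system and options for
#'   later re-evaluation.
#' @export
scaling_curve <- function(system, factors, omegas, samples = NULL, ...) {
  stopifnot(inherits(system, "shift_system"))
  if (length(factors) == 0L) stop("empty factor list")
  if (length(omegas) == 0L) stop("empty Omega list")
  if (is.unsorted(factors, strictly = TRUE))
    stop("`factors` must be strictly increasing")
  gamma_g <- gamma_prefactor(system$ground_state, system$solvent, 0)
  gammas_e <- lapply(omegas, function(w)
    gamma_prefactor(system$excited_state, system$solvent, w))
  opts <- list(...)
  run_integral <- function(wf, st, factor, sample) {
    cav <- build_cavity(system$atoms, system$solvent$name, scale = factor)
    do.call(.exterior_s2_integral,
            c(list(wf = wf, cavity = cav, damping = damping_spec(st$b),
                   sample = sample),
              opts, if (is.null(opts$method)) list(method = "auto")))
  }
  ng <- length(factors)
  ground_eV <- ground_err <- numeric(ng)
  excited_eV <- excited_err <- matrix(NA_real_, ng, length(omegas))
  for (i in seq_along(factors)) {
    ig <- run_integral(system$ground_wf, system$ground_state, factors[i],
                       samples$ground)
    ground_eV[i] <- hartree_to_ev(-gamma_g$value * ig$total)
    ground_err[i] <- hartree_to_ev(abs(gamma_g$value) * ig$mc_error)
    ie <- run_integral(system$excited_wf, system$excited_state, factors[i],
                       samples$excited)
    for (j in seq_along(omegas)) {
      excited_eV[i, j] <- hartree_to_ev(-gammas_e[[j]]$value * ie$total)
      excited_err[i, j] <- hartree_to_ev(abs(gammas_e[[j]]$value) *
                                           ie$mc_error)
    }
  }
  structure(list(factors = factors, omegas = omegas,
                 ground_eV = ground_eV, excited_eV = excited_eV,
                 ground_err_eV = ground_err, excited_err_eV = excited_err,
                 system = system, samples = samples, opts = opts),
            class = "scaling_curve")
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat("Cavity-scaling curve over", length(x$factors), "factor(s) and",
      length(x$omegas), "Omega value(s)\n")
  df <- data.frame(factor = x$factors, ground_eV = x$ground_eV)
  for (j in seq_along(x$omegas))
    df[[sprintf("excited_eV(Omega=%g)", x$omegas[j])]] <- x$excited_eV[, j]
  print(df, digits = 4)
  invisible(x)
}

#' Export a scaling curve as a plot-ready table
#'
#' @param curve a [scaling_curve()].
#' @param path output file (tab-separated).
#' @export
write_scaling_curve <- function(curve, path) {
  df <- data.frame(factor = curve$factors, ground_eV = curve$ground_eV)
  for (j in seq_along(curve$omegas))
    df[[sprintf("excited_eV_omega_%g", curve$omegas[j])]] <-
      curve$excited_eV[, j]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Anchor the shift to a reference ground-state dispersion energy
#'
#' Finds the cavity scale factor at which the ground-state dispersion free
#' energy equals an externally computed reference value (monotone
#' interpolation of the ground curve plus root refinement; no extrapolation
#' outside the sampled factor range) and evaluates the solvatochromic shift
#' at that scale.
#'
#' @param curve a [scaling_curve()].
#' @param reference_eV reference ground-state dispersion free energy (eV,
#'   negative), within the range of the ground curve.
#' @param omega_eV Omega for the shift at the anchored scale; defaults to
#'   the first Omega of the curve.
#' @return list with `scale` and `shift` (a `"shift_result"`).
#' @export
anchor_to_reference <- function(curve, reference_eV, omega_eV = NULL) {
  stopifnot(inherits(curve, "scaling_curve"))
  g <- curve$ground_eV
  if (reference_eV < min(g) || reference_eV > max(g))
    stop(sprintf(
      "reference %.4f eV outside the ground-curve range [%.4f, %.4f] eV",
      reference_eV, min(g), max(g)))
  if (is.null(omega_eV)) omega_eV <- curve$omegas[1L]
  if (length(curve$factors) == 1L) {
    scale <- curve$factors
  } else {
    fit <- stats::splinefun(curve$factors, g, method = "monoH.FC")
    scale <- stats::uniroot(function(f) fit(f) - reference_eV,
                            range(curve$factors), tol = 1e-10)$root
  }
  sys <- curve$system
  args <- c(curve$opts, if (is.null(curve$opts$method))
    list(method = "auto"))
  gnd <- do.call(.system_dg, c(list(system = sys, factor = scale,
                                    omega_eV = 0, state = "ground",
                                    sample = curve$samples$ground), args))
  exc <- do.call(.system_dg, c(list(system = sys, factor = scale,
                                    omega_eV = omega_eV, state = "excited",
                                    sample = curve$samples$excited), args))
  list(scale = scale, shift = solvatochromic_shift(gnd, exc),
       reference_eV = reference_eV)
}
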