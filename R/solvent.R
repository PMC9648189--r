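# Solvent model: frequency-dependent refractive index, Clausius--Mossotti
# response, validation of the auxiliary frequency Omega, and the dispersion
# prefactor Gamma(Omega).

#' Packaged solvent dispersion data
#'
#' The six supported solvents with their static refractive index `eta0`, the
#' quadratic/quartic coefficients `A2` (per eV^2) and `A4` (per eV^4) of the
#' refractive-index dispersion formula, the experimental ionization potential
#' (Hartree), and the onset of solvent electronic absorption
#' (`first_absorption_eV`).  Only the cyclohexane onset (7.44 eV) is part of
#' the packaged data; the others are `NA` and must be supplied by the user
#' (they are inputs of the method, typically taken from a computed or
#' measured solvent UV spectrum).
#'
#' @return data frame with one row per solvent.
#' @export
load_solvents <- function() {
  utils::read.delim(.extdata("solvents.tsv"), stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Construct a solvent model
#'
#' @param name a solvent in [load_solvents()], or any name when all
#'   parameters are supplied.
#' @param eta0,A2,A4,ionization_potential,first_absorption overrides for the
#'   packaged values: static refractive index, dispersion-fit coefficients
#'   (per eV^2 / per eV^4), ionization potential (Hartree), absorption onset
#'   (eV).
#' @param eta_omega optional direct override of the refractive index at the
#'   working frequency (used when the polynomial fit is extrapolated beyond
#'   its validity, e.g. 1.60 for cyclohexane at 172 nm).
#' @return object of class `"solvent_model"`.
#' @export
solvent_model <- function(name, eta0 = NULL, A2 = NULL, A4 = NULL,
                          ionization_potential = NULL,
                          first_absorption = NULL, eta_omega = NULL) {
  tab <- load_solvents()
  row <- tab[tab$name == name, ]
  take <- function(override, col) {
    if (!is.null(override)) override
    else if (nrow(row) == 1L) row[[col]]
    else stop("solvent '", name, "' is not packaged; supply `", col, "`")
  }
  s <- structure(list(
    name = name,
    eta0 = take(eta0, "eta0"),
    A2 = take(A2, "A2"),
    A4 = take(A4, "A4"),
    ionization_potential = take(ionization_potential, "ionization_hartree"),
    first_absorption = if (!is.null(first_absorption)) first_absorption
      else if (nrow(row) == 1L) row$first_absorption_eV else NA_real_,
    eta_omega = eta_omega
  ), class = "solvent_model")
  if (!is.finite(s$eta0) || s$eta0 <= 1) stop("`eta0` must be > 1")
  if (!is.finite(s$ionization_potential) || s$ionization_potential <= 0)
    stop("`ionization_potential` must be > 0 (Hartree)")
  if (!is.na(s$first_absorption) && s$first_absorption <= 0)
    stop("`first_absorption` must be > 0 (eV)")
  s
}

#' @export
print.solvent_model <- function(x, ...) {
  cat("Solvent:", x$name, "\n")
  cat(sprintf("  eta(0) = %.5f, A2 = %.6g /eV^2, A4 = %.6g /eV^4\n",
              x$eta0, x$A2, x$A4))
  cat(sprintf("  I = %.4f Hartree, absorption onset = %s eV\n",
              x$ionization_potential,
              ifelse(is.na(x$first_absorption), "unset",
                     format(x$first_absorption))))
  if (!is.null(x$eta_omega))
    cat(sprintf("  eta(Omega) override: %.4f\n", x$eta_omega))
  invisible(x)
}

#' Frequency-dependent refractive index
#'
#' Evaluates the dispersion polynomial
#' `eta(Omega) = eta(0) + A2 Omega^2 + A4 Omega^4` (Omega in eV) with the
#' solvent's fitted coefficients.  If the solvent carries an `eta_omega`
#' override it is returned for any positive frequency (use this when the fit
#' is extrapolated beyond the data that produced it).
#'
#' @param solvent a [solvent_model()].
#' @param omega_eV frequency in eV, >= 0.
#' @param use_override honour the solvent's `eta_omega` override.
#' @return refractive index (dimensionless).
#' @export
refractive_index <- function(solvent, omega_eV, use_override = TRUE) {
  stopifnot(inherits(solvent, "solvent_model"))
  if (any(!is.finite(omega_eV)) || any(omega_eV < 0))
    stop("`omega_eV` must be >= 0")
  if (use_override && !is.null(solvent$eta_omega) && any(omega_eV > 0)) {
    out <- rep(solvent$eta0, length(omega_eV))
    out[omega_eV > 0] <- solvent$eta_omega
    return(out)
  }
  if (!is.na(solvent$first_absorption) &&
      any(omega_eV > solvent$first_absorption))
    warning("frequency above the solvent absorption onset; ",
            "the dispersion fit is not reliable there")
  solvent$eta0 + solvent$A2 * omega_eV^2 + solvent$A4 * omega_eV^4
}

#' Clausius--Mossotti factor
#'
#' The ratio `(eta^2 - 1) / (eta^2 + 2)` linking the refractive index to the
#' molecular polarizability density of the medium.
#'
#' @param eta refractive index, >= 1.
#' @return dimensionless factor in `[0, 1)`.
#' @export
clausius_mossotti <- function(eta) {
  if (any(!is.finite(eta)) || any(eta < 1)) stop("`eta` must be >= 1")
  (eta^2 - 1) / (eta^2 + 2)
}

#' Validate the auxiliary frequency Omega
#'
#' For a ground-state solute only `Omega = 0` is admissible.  For an excited
#' solute, `Omega` must lie strictly between the solute vertical transition
#' energy and the solvent's first absorption energy: the de-excitation of the
#' solute must not be able to excite the solvent, and the shifted
#' Casimir--Polder denominators must stay positive.
#'
#' @param omega_eV proposed Omega (eV).
#' @param solute_state an [electronic_state()].
#' @param solvent a [solvent_model()] (its `first_absorption` must be set for
#'   excited states).
#' @return object of class `"omega_choice"` with fields `omega` and
#'   `valid_interval`.
#' @export
validate_omega <- function(omega_eV, solute_state, solvent) {
  stopifnot(inherits(solute_state, "electronic_state"),
            inherits(solvent, "solvent_model"))
  if (solute_state$label == "ground") {
    if (omega_eV != 0)
      stop("ground-state solute requires Omega = 0 (got ", omega_eV, " eV)")
    return(structure(list(omega = 0, valid_interval = c(0, 0),
                          state_label = "ground"),
                     class = "omega_choice"))
  }
  lo <- solute_state$vertical_transition_energy
  hi <- solvent$first_absorption
  if (is.na(hi))
    stop("solvent '", solvent$name, "' has no absorption onset; supply ",
         "`first_absorption` to the solvent model")
  if (!(omega_eV > lo && omega_eV < hi))
    stop(sprintf(
      "Omega = %g eV outside the admissible interval (%g, %g) eV", omega_eV,
      lo, hi))
  structure(list(omega = omega_eV, valid_interval = c(lo, hi),
                 state_label = "excited"),
            class = "omega_choice")
}

#' Dispersion prefactor Gamma(Omega)
#'
#' Assembles the Casimir--Polder prefactor that multiplies the exterior
#' integral of `S^2(r)` in the dispersion free energy:
#' \deqn{\Gamma(\Omega) = \frac{3}{8\pi}\,\frac{W_B}{W_A + W_B}
#'   \Big[ 2\, CM(\eta(\Omega)) - CM(\eta(0))\,\frac{I_B}{I_B + \Omega} \Big]}
#' with `CM` the Clausius--Mossotti factor, `I_A` the solute-state ionization
#' potential, `I_B` the solvent one, and the shifted closure parameters
#' `W_A = I_A + Omega`, `W_B = I_B - Omega` (the method is inapplicable if
#' either is nonpositive).  Both the static and the Omega-frequency solvent
#' polarizabilities enter through their Clausius--Mossotti factors.  The
#' bracket exceeds `CM(eta(0)) (2 - I_B/(I_B+Omega)) > 0`, so `Gamma > 0`
#' whenever `W_A, W_B > 0` and the dispersion interaction stays attractive.
#' At `Omega = 0` the expression reduces exactly to the ground-state form
#' `(3/8 pi) CM(eta(0)) I_B / (I_A + I_B)`.
#'
#' @param solute_state an [electronic_state()].
#' @param solvent a [solvent_model()].
#' @param omega an [validate_omega()] result, or a numeric Omega in eV
#'   (validated internally).
#' @param eta_omega optional direct refractive-index value at Omega,
#'   overriding the dispersion fit.
#' @return object of class `"gamma_prefactor"`: `value` (atomic units) and a
#'   `components` list (`cm0`, `cm_omega`, `W_A`, `W_B`, `omega_A`,
#'   `omega_B`, `eta0`, `eta_omega`, `omega_eV`).
#' @export
gamma_prefactor <- function(solute_state, solvent, omega, eta_omega = NULL) {
  stopifnot(inherits(solute_state, "electronic_state"),
            inherits(solvent, "solvent_model"))
  if (!inherits(omega, "omega_choice"))
    omega <- validate_omega(omega, solute_state, solvent)
  w_ha <- ev_to_hartree(omega$omega)
  IA <- solute_state$ionization_potential
  IB <- solvent$ionization_potential
  WA <- IA + w_ha
  WB <- IB - w_ha
  if (WA <= 0 || WB <= 0)
    stop("shifted closure parameter nonpositive (W_A = ", signif(WA, 4),
         ", W_B = ", signif(WB, 4), " Hartree); method inapplicable")
  eta0 <- solvent$eta0
  etaW <- if (!is.null(eta_omega)) eta_omega
    else refractive_index(solvent, omega$omega)
  cm0 <- clausius_mossotti(eta0)
  cmW <- clausius_mossotti(etaW)
  value <- 3 / (8 * pi) * WB / (WA + WB) *
    (2 * cmW - cm0 * IB / (IB + w_ha))
  structure(list(
    value = value,
    components = list(cm0 = cm0, cm_omega = cmW, W_A = WA, W_B = WB,
                      omega_A = IA, omega_B = IB, eta0 = eta0,
                      eta_omega = etaW, omega_eV = omega$omega),
    solvent_name = solvent$name,
    state_label = solute_state$label
  ), class = "gamma_prefactor")
}

#' @export
print.gamma_prefactor <- function(x, ...) {
  cat(sprintf("Gamma(Omega = %g eV) = %.6e a.u. [%s state, %s]\n",
              x$components$omega_eV, x$value, x$state_label, x$solvent_name))
  with(x$components, cat(sprintf(
    "  CM(eta0 = %.5f) = %.5f, CM(eta(Omega) = %.5f) = %.5f\n  W_A = %.4f, W_B = %.4f Hartree\n",
    eta0, cm0, eta_omega, cm_omega, W_A, W_B)))
  invisible(x)
}
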