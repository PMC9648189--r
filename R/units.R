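# Physical constants (CODATA 2018), recorded once and used everywhere a
# conversion crosses the interface boundary.  Internal energies are Hartree,
# internal lengths bohr.
.const <- list(
  ev_per_hartree = 27.211386,     # 1 Hartree in eV
  cm1_per_ev     = 8065.543937,   # 1 eV in cm^-1
  nm_ev          = 1239.841984,   # hc in eV * nm  (E[eV] = nm_ev / lambda[nm])
  bohr_per_ang   = 1 / 0.529177210903
)

#' Convert between spectroscopic energy/wavelength units
#'
#' Exact interconversion between Hartree, electron-volt, wavenumber and
#' wavelength units with fixed CODATA constants (1 Hartree = 27.211386 eV,
#' 1 eV = 8065.543937 cm^-1, hc = 1239.841984 eV nm).  Wavelengths are
#' reciprocal in energy, so `nm` values convert through `E = hc / lambda`.
#'
#' @param value numeric vector of values to convert.
#' @param from,to one of `"hartree"`, `"eV"`, `"cm-1"`, `"nm"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_units(6.93, "eV", "cm-1")   # ~55,894
#' convert_units(172, "nm", "cm-1")    # ~58,140
#' @export
convert_units <- function(value, from, to) {
  units <- c("hartree", "eV", "cm-1", "nm")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(value)
  to_ev <- switch(from,
    "hartree" = value * .const$ev_per_hartree,
    "eV"      = value,
    "cm-1"    = value / .const$cm1_per_ev,
    "nm"      = .const$nm_ev / value
  )
  switch(to,
    "hartree" = to_ev / .const$ev_per_hartree,
    "eV"      = to_ev,
    "cm-1"    = to_ev * .const$cm1_per_ev,
    "nm"      = .const$nm_ev / to_ev
  )
}

ev_to_hartree <- function(x) x / .const$ev_per_hartree
hartree_to_ev <- function(x) x * .const$ev_per_hartree
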