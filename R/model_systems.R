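# Model electronic systems: analytic densities, a Metropolis sampler producing
# electron-configuration snapshots, and the escape-fraction estimator for the
# damping parameter b.

.element_charges <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                      O = 8, F = 9, Ne = 10, S = 16, Cl = 17)

#' Create a solute atom
#'
#' @param element chemical symbol (e.g. `"C"`).
#' @param position numeric length-3 position in bohr.
#' @param nuclear_charge positive nuclear charge; looked up from the element
#'   symbol when omitted.
#' @return an object of class `"atom"`.
#' @export
atom <- function(element, position, nuclear_charge = NULL) {
  stopifnot(is.character(element), length(element) == 1L)
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position)))
    stop("`position` must be a finite 3-vector (bohr)")
  if (is.null(nuclear_charge)) {
    nuclear_charge <- unname(.element_charges[element])
    if (is.na(nuclear_charge))
      stop("unknown element '", element, "'; supply `nuclear_charge`")
  }
  if (!is.finite(nuclear_charge) || nuclear_charge <= 0)
    stop("`nuclear_charge` must be > 0")
  structure(list(element = element, position = position,
                 nuclear_charge = as.numeric(nuclear_charge)),
            class = "atom")
}

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z` rows.
#' Coordinates are taken as Angstrom unless the comment line contains the tag
#' `bohr` (or `au`), or `unit` is given explicitly; positions are returned in
#' bohr.
#'
#' @param path file path.
#' @param unit `"angstrom"`, `"bohr"`, or `NULL` to read the tag from the
#'   comment line.
#' @return list of [atom()] objects.
#' @export
read_xyz <- function(path, unit = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a valid XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 1L) stop("invalid atom count in XYZ file")
  comment <- lines[[2L]]
  if (is.null(unit)) {
    unit <- if (grepl("\\b(bohr|au|a\\.u\\.)\\b", tolower(comment)))
      "bohr" else "angstrom"
  }
  unit <- match.arg(unit, c("angstrom", "bohr"))
  rows <- lines[3:(2L + n)]
  fac <- if (unit == "angstrom") .const$bohr_per_ang else 1
  lapply(rows, function(row) {
    f <- strsplit(trimws(row), "\\s+")[[1L]]
    if (length(f) < 4L) stop("malformed XYZ row: ", row)
    atom(f[[1L]], as.numeric(f[2:4]) * fac)
  })
}

## ---- marginal one-electron densities ---------------------------------------

# A marginal is an isotropic one-electron density about a center:
#   kind "gaussian"   parameter sd (bohr)
#   kind "hydrogenic" parameter Z  (1s density Z^3/pi exp(-2 Z r))
#   kind "point"      delta at the center (used by degenerate oracle cases)
.marginal <- function(kind, center, sd = NULL, Z = NULL) {
  list(kind = kind, center = as.numeric(center), sd = sd, Z = Z)
}

.marginal_log_density <- function(marg, X) {
  # X: m x 3 matrix of positions (bohr)
  d <- sweep(X, 2L, marg$center)
  r2 <- rowSums(d * d)
  switch(marg$kind,
    gaussian = -1.5 * log(2 * pi * marg$sd^2) - r2 / (2 * marg$sd^2),
    hydrogenic = log(marg$Z^3 / pi) - 2 * marg$Z * sqrt(r2),
    stop("marginal kind '", marg$kind, "' has no continuous density")
  )
}

# P(|x - center| > a), closed form per kind.
.marginal_tail <- function(marg, a) {
  a <- pmax(a, 0)
  switch(marg$kind,
    gaussian = {
      z <- a / marg$sd
      2 * stats::pnorm(z, lower.tail = FALSE) +
        sqrt(2 / pi) * z * exp(-z^2 / 2)
    },
    hydrogenic = {
      t <- 2 * marg$Z * a
      exp(-t) * (1 + t + t^2 / 2)
    },
    point = as.numeric(a <= 0),
    stop("unknown marginal kind")
  )
}

# Second moment <|x - center|^2> of the marginal (bohr^2).
.marginal_second_moment <- function(marg) {
  switch(marg$kind,
    gaussian = 3 * marg$sd^2,
    hydrogenic = 3 / marg$Z^2,
    point = 0,
    stop("unknown marginal kind")
  )
}

## ---- model wavefunctions ---------------------------------------------------

#' Construct a model electronic wavefunction
#'
#' The density is a product of independent one-electron marginals (this covers
#' all packaged model systems); user-supplied joint densities can be passed via
#' `log_density` with `marginals = NULL`, in which case only Monte Carlo
#' operations are available.
#'
#' @param n_electrons positive integer.
#' @param log_density function mapping an `m x (3 n_electrons)` configuration
#'   matrix (electron coordinates concatenated per row) to a length-`m` vector
#'   of log densities.  Derived from `marginals` when omitted.
#' @param marginals list of per-electron marginal specifications (internal
#'   format; use the convenience constructors for standard models).
#' @param state_label `"ground"` or `"excited"`.
#' @param center_of_charge electronic center of charge (bohr); computed from
#'   the marginals when available.
#' @return object of class `"model_wavefunction"`.
#' @seealso [gaussian_wavefunction()], [hydrogenic_wavefunction()],
#'   [make_two_state_fixture()]
#' @export
model_wavefunction <- function(n_electrons, log_density = NULL,
                               marginals = NULL,
                               state_label = c("ground", "excited"),
                               center_of_charge = NULL) {
  state_label <- match.arg(state_label)
  n_electrons <- as.integer(n_electrons)
  stopifnot(n_electrons >= 1L)
  if (is.null(log_density)) {
    if (is.null(marginals)) stop("supply `log_density` or `marginals`")
    margs <- marginals
    log_density <- function(X) {
      out <- 0
      for (e in seq_along(margs))
        out <- out + .marginal_log_density(margs[[e]], X[, (3 * e - 2):(3 * e),
                                                         drop = FALSE])
      out
    }
  }
  if (!is.null(marginals) && length(marginals) != n_electrons)
    stop("need one marginal per electron")
  if (is.null(center_of_charge)) {
    if (is.null(marginals))
      stop("supply `center_of_charge` when no marginals are given")
    centers <- vapply(marginals, `[[`, numeric(3), "center")
    center_of_charge <- rowMeans(matrix(centers, nrow = 3L))
  }
  structure(list(
    n_electrons = n_electrons,
    log_density = log_density,
    marginals = marginals,
    has_analytic_marginals = !is.null(marginals),
    state_label = state_label,
    center_of_charge = as.numeric(center_of_charge)
  ), class = "model_wavefunction")
}

#' @export
print.model_wavefunction <- function(x, ...) {
  cat("Model wavefunction:", x$n_electrons, "electron(s),",
      x$state_label, "state\n")
  if (x$has_analytic_marginals) {
    kinds <- vapply(x$marginals, `[[`, character(1), "kind")
    cat("  analytic marginals:", paste(kinds, collapse = ", "), "\n")
  }
  cat("  center of charge:",
      paste(sprintf("%.4f", x$center_of_charge), collapse = " "), "bohr\n")
  invisible(x)
}

#' Isotropic Gaussian one-electron model density
#'
#' @param sd standard deviation per Cartesian axis (bohr).
#' @param center center (bohr).
#' @param state_label `"ground"` or `"excited"`.
#' @export
gaussian_wavefunction <- function(sd = 1, center = c(0, 0, 0),
                                  state_label = "ground") {
  stopifnot(sd > 0)
  model_wavefunction(1L, marginals = list(.marginal("gaussian", center,
                                                    sd = sd)),
                     state_label = state_label)
}

#' Hydrogen-like 1s one-electron model density
#'
#' Density proportional to `exp(-2 Z r)`, the square of the 1s orbital of a
#' one-electron ion of nuclear charge `Z`.
#'
#' @param Z effective nuclear charge (> 0).
#' @param center nucleus position (bohr).
#' @param state_label `"ground"` or `"excited"`.
#' @export
hydrogenic_wavefunction <- function(Z = 1, center = c(0, 0, 0),
                                    state_label = "ground") {
  stopifnot(Z > 0)
  model_wavefunction(1L, marginals = list(.marginal("hydrogenic", center,
                                                    Z = Z)),
                     state_label = state_label)
}

#' Product wavefunction of independent one-electron marginals
#'
#' @param marginals list of marginal specs (e.g. taken from other model
#'   wavefunctions' `$marginals`).
#' @param state_label `"ground"` or `"excited"`.
#' @export
product_wavefunction <- function(marginals, state_label = "ground") {
  model_wavefunction(length(marginals), marginals = marginals,
                     state_label = state_label)
}

#' Synthetic ground/excited model pair
#'
#' Builds a pair of normalized isotropic Gaussian one-electron densities in
#' which the excited state is strictly more diffuse than the ground state:
#' its per-axis standard deviation is `diffuseness_ratio` times the ground
#' one, so second moments scale with the ratio squared.  This is the package's
#' stand-in for a correlated ground/excited wavefunction pair of a carbonyl
#' chromophore and exercises every stage of the shift pipeline.
#'
#' @param diffuseness_ratio length scale ratio excited/ground, must be > 1.
#' @param sd_ground ground-state standard deviation per axis (bohr).
#' @param center common center (bohr).
#' @return list with elements `ground` and `excited`.
#' @export
make_two_state_fixture <- function(diffuseness_ratio, sd_ground = 1,
                                   center = c(0, 0, 0)) {
  if (!is.numeric(diffuseness_ratio) || diffuseness_ratio <= 1)
    stop("`diffuseness_ratio` must be > 1")
  list(
    ground = gaussian_wavefunction(sd_ground, center, "ground"),
    excited = gaussian_wavefunction(sd_ground * diffuseness_ratio, center,
                                    "excited")
  )
}

#' Electronic state parameters
#'
#' Bundles the per-state quantities the dispersion model needs: the ionization
#' potential (Hartree), the vertical transition energy from the ground state
#' (eV; 0 for the ground state itself) and the damping parameter b
#' (inverse bohr).
#'
#' @param label `"ground"` or `"excited"`.
#' @param ionization_potential Hartree, > 0.
#' @param vertical_transition_energy eV, >= 0 (0 for a ground state).
#' @param b damping parameter (1/bohr), > 0.
#' @export
electronic_state <- function(label = c("ground", "excited"),
                             ionization_potential,
                             vertical_transition_energy = 0,
                             b) {
  label <- match.arg(label)
  if (!is.finite(ionization_potential) || ionization_potential <= 0)
    stop("`ionization_potential` must be > 0 (Hartree)")
  if (!is.finite(vertical_transition_energy) ||
      vertical_transition_energy < 0)
    stop("`vertical_transition_energy` must be >= 0 (eV)")
  if (label == "ground" && vertical_transition_energy != 0)
    stop("a ground state has zero vertical transition energy")
  if (!is.finite(b) || b <= 0) stop("`b` must be > 0 (1/bohr)")
  structure(list(label = label,
                 ionization_potential = ionization_potential,
                 vertical_transition_energy = vertical_transition_energy,
                 b = b),
            class = "electronic_state")
}

## ---- Metropolis sampler ----------------------------------------------------

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Sample electron configurations from a model density
#'
#' Metropolis Monte Carlo targeting the electronic density: single-electron
#' moves with isotropic Gaussian proposals, run over an ensemble of
#' independent walkers.  One "step" is a sweep of one attempted move per
#' electron.  Identical seeds give bitwise-identical snapshots.
#'
#' @param wf a [model_wavefunction()].
#' @param n number of configuration snapshots to keep (>= 1).
#' @param seed integer RNG seed.
#' @param step_size Gaussian proposal standard deviation (bohr), > 0.
#' @param burn_in equilibration sweeps discarded per walker.
#' @param stride sweeps between kept snapshots (decorrelation stride).
#' @param n_walkers number of independent walkers.
#' @return object of class `"configuration_sample"` with fields `snapshots`
#'   (array `n x n_electrons x 3`), `walker` (walker index per snapshot, all
#'   snapshots of one walker forming one chain), `seed`, `n_kept`,
#'   `acceptance_rate`, `decorrelation_stride`.
#' @export
sample_configurations <- function(wf, n, seed, step_size = 1,
                                  burn_in = 1000L, stride = 10L,
                                  n_walkers = 100L) {
  stopifnot(inherits(wf, "model_wavefunction"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  if (!is.finite(step_size) || step_size <= 0)
    stop("`step_size` must be > 0")
  stride <- max(1L, as.integer(stride))
  burn_in <- max(0L, as.integer(burn_in))
  m <- min(as.integer(n_walkers), n)
  ne <- wf$n_electrons
  keep_per <- ceiling(n / m)

  .with_seed(seed, {
    # start walkers near the center(s) of the density
    if (wf$has_analytic_marginals) {
      X <- matrix(0, m, 3L * ne)
      for (e in seq_len(ne)) {
        ctr <- wf$marginals[[e]]$center
        X[, (3 * e - 2):(3 * e)] <-
          matrix(stats::rnorm(3L * m), m, 3L) +
          matrix(ctr, m, 3L, byrow = TRUE)
      }
    } else {
      X <- matrix(stats::rnorm(3L * ne * m), m, 3L * ne) +
        matrix(rep(wf$center_of_charge, ne), m, 3L * ne, byrow = TRUE)
    }
    ld <- wf$log_density(X)
    if (any(!is.finite(ld) & ld > 0) || any(is.nan(ld)))
      stop("density is not evaluable (non-finite log density at start)")

    n_acc <- 0; n_try <- 0
    sweeps_total <- burn_in + keep_per * stride
    snaps <- array(NA_real_, c(m * keep_per, ne, 3L))
    kept <- 0L
    for (sweep in seq_len(sweeps_total)) {
      for (e in seq_len(ne)) {
        cols <- (3 * e - 2):(3 * e)
        prop <- X
        prop[, cols] <- prop[, cols] + step_size * matrix(stats::rnorm(3L * m),
                                                          m, 3L)
        ld_prop <- wf$log_density(prop)
        if (any(is.nan(ld_prop)) || any(ld_prop > 700))
          stop("density diverged during sampling (non-normalizable density?)")
        acc <- log(stats::runif(m)) < (ld_prop - ld)
        X[acc, ] <- prop[acc, ]
        ld[acc] <- ld_prop[acc]
        if (sweep > burn_in) {
          n_acc <- n_acc + sum(acc); n_try <- n_try + m
        }
      }
      if (sweep > burn_in && (sweep - burn_in) %% stride == 0L) {
        idx <- kept * m + seq_len(m)
        for (e in seq_len(ne))
          snaps[idx, e, ] <- X[, (3 * e - 2):(3 * e)]
        kept <- kept + 1L
      }
    }
    walker <- rep(seq_len(m), times = keep_per)
    keep_idx <- seq_len(n)
    structure(list(
      snapshots = snaps[keep_idx, , , drop = FALSE],
      walker = walker[keep_idx],
      seed = seed,
      n_kept = n,
      acceptance_rate = n_acc / n_try,
      decorrelation_stride = stride,
      step_size = step_size,
      burn_in = burn_in,
      n_walkers = m
    ), class = "configuration_sample")
  })
}

#' @export
print.configuration_sample <- function(x, ...) {
  cat("Configuration sample:", x$n_kept, "snapshots,",
      dim(x$snapshots)[2L], "electron(s),", x$n_walkers, "walkers\n")
  cat(sprintf("  seed %d, stride %d, acceptance rate %.3f\n",
              x$seed, x$decorrelation_stride, x$acceptance_rate))
  invisible(x)
}

## ---- escape-fraction estimator for b --------------------------------------

# Volume of the lens-shaped intersection of two equal spheres of radius R at
# center distance d (0 when disjoint).
.lens_volume <- function(R, d) {
  if (d >= 2 * R) return(0)
  pi * (2 * R - d)^2 * (d + 4 * R) / 12
}

.effective_sphere_count <- function(centers, R) {
  N <- nrow(centers)
  if (N == 1L) return(1)
  vs <- 4 / 3 * pi * R^3
  overlap <- 0
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    overlap <- overlap + .lens_volume(R, d) / vs
  }
  N - min(N - 1, overlap)
}

# Electron count escaping the union of equal spheres of radius R centered on
# `centers`, for a product wavefunction.  Angular quadrature about each
# marginal center with the closed-form radial tail of the marginal; assumes
# the sphere union is star-shaped as seen from each marginal center (true for
# interlocking spheres around compact densities).
.escape_fraction <- function(wf, centers, R, angular = NULL) {
  total <- 0
  for (marg in wf$marginals) {
    rel <- sweep(centers, 2L, marg$center)  # sphere centers in marginal frame
    if (nrow(centers) == 1L && sqrt(sum(rel[1L, ]^2)) < 1e-12) {
      total <- total + .marginal_tail(marg, R)
      next
    }
    proj <- angular$dirs %*% t(rel)                   # ndir x nsph
    disc <- proj^2 - matrix(rowSums(rel^2), nrow(proj), nrow(rel),
                            byrow = TRUE) + R^2
    t_far <- ifelse(disc >= 0, proj + sqrt(pmax(disc, 0)), 0)
    r_exit <- pmax(apply(t_far, 1L, max), 0)
    total <- total + sum(angular$w * .marginal_tail(marg, r_exit)) / (4 * pi)
  }
  total
}

.angular_grid <- function(order) {
  gl <- pracma::gaussLegendre(order, -1, 1)
  nphi <- 2L * order
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- rep(phi, times = order)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  list(dirs = dirs, w = w)  # weights sum to 4*pi
}

# Half-strength point of the field damping function: x such that f2(x) = 1/2.
.f2_half_point <- function() {
  stats::uniroot(function(x) f2_damping(x) - 0.5, c(1, 5),
                 tol = 1e-12)$root
}

#' Estimate the damping parameter b from the electron escape fraction
#'
#' Finds the common radius `R` of equal hard spheres centered on the heavy
#' atoms such that the number of electrons outside the union of spheres equals
#' a target of 0.5 electrons per sphere, with the sphere count reduced by the
#' summed pairwise overlap volume fractions (capped at one less than the
#' sphere count) to account for interlocking spheres.  The radius is then
#' mapped to the damping parameter through a monotone empirical map, by
#' default `b = x50 / R` where `x50 ~ 2.674` is the argument at which the
#' damping function reaches half strength — i.e. the damping switches on at
#' the escape-radius boundary.  Supply `b_map` to override the map.
#'
#' @param wf a [model_wavefunction()] with analytic marginals.
#' @param heavy_centers list of [atom()]s (or an `n x 3` matrix of positions,
#'   bohr) carrying the sphere centers.
#' @param target_fraction electrons escaping per effective sphere (default
#'   0.5).
#' @param b_map function mapping the radius (bohr) to b (1/bohr).
#' @param tol tolerance on |escape fraction - target| (electrons).
#' @param angular_order order of the angular quadrature used for
#'   multi-center escape fractions.
#' @return list with `b`, `radius`, `escape_fraction`, `target`,
#'   `effective_spheres`.
#' @export
estimate_b <- function(wf, heavy_centers, target_fraction = 0.5,
                       b_map = NULL, tol = 1e-6, angular_order = 48L) {
  stopifnot(inherits(wf, "model_wavefunction"))
  if (!wf$has_analytic_marginals)
    stop("escape-fraction estimation needs analytic marginals")
  if (inherits(heavy_centers, "atom")) heavy_centers <- list(heavy_centers)
  if (is.list(heavy_centers)) {
    if (length(heavy_centers) == 0L) stop("need at least one heavy center")
    centers <- t(vapply(heavy_centers, function(a) {
      if (inherits(a, "atom")) a$position else as.numeric(a)
    }, numeric(3)))
  } else {
    centers <- matrix(heavy_centers, ncol = 3L)
  }
  if (nrow(centers) == 0L) stop("need at least one heavy center")
  ang <- .angular_grid(angular_order)

  g <- function(R) {
    .escape_fraction(wf, centers, R, ang) -
      target_fraction * .effective_sphere_count(centers, R)
  }
  r_lo <- 1e-4
  if (g(r_lo) <= 0)
    stop("escape target unattainable: too few electrons for the sphere count")
  r_hi <- 2
  it <- 0L
  while (g(r_hi) > 0) {
    r_hi <- r_hi * 2
    it <- it + 1L
    if (it > 40L)
      stop("density too diffuse: no finite radius reaches the escape target")
  }
  root <- stats::uniroot(g, c(r_lo, r_hi), tol = 1e-12)$root
  esc <- .escape_fraction(wf, centers, root, ang)
  neff <- .effective_sphere_count(centers, root)
  if (abs(esc - target_fraction * neff) > tol)
    stop("bisection failed to reach the escape tolerance")
  if (is.null(b_map)) {
    x50 <- .f2_half_point()
    b_map <- function(R) x50 / R
  }
  list(b = b_map(root), radius = root, escape_fraction = esc,
       target = target_fraction * neff, effective_spheres = neff)
}
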