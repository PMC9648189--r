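# Damped electronic electric fields at probe points, directional variances
# and the fluctuation strength S^2(r), with a deterministic quadrature oracle
# for product model densities.

#' Field damping specification
#'
#' The electronic electric field entering the fluctuation measure is damped at
#' short range by the incomplete-gamma (Tang--Toennies) factor of order two,
#' `f2(x) = 1 - exp(-x)(1 + x + x^2/2)` with `x = b r`, applied to each
#' electron--probe distance.  `f2` rises from 0 like `x^3/6` — cancelling the
#' `1/r^2` Coulomb field singularity — and tends to 1 at long range.
#'
#' @param b damping parameter (1/bohr), > 0.
#' @param form damping family identifier (only `"tang-toennies-2"`).
#' @export
damping_spec <- function(b, form = "tang-toennies-2") {
  if (!is.numeric(b) || !is.finite(b) || b <= 0) stop("`b` must be > 0")
  form <- match.arg(form)
  structure(list(b = b, form = form), class = "damping_spec")
}

#' Damping factor f2
#'
#' @param x nonnegative numeric vector (`b * r`).
#' @return values in `[0, 1]`.
#' @export
f2_damping <- function(x) {
  out <- numeric(length(x))
  small <- x < 0.1
  if (any(small)) {
    xs <- x[small]
    # f2(x) = exp(-x) * sum_{k>=3} x^k/k!; truncated series, rel err < 1e-16
    ser <- xs^3 / 6 * (1 + xs / 4 * (1 + xs / 5 * (1 + xs / 6 *
             (1 + xs / 7 * (1 + xs / 8)))))
    out[small] <- exp(-xs) * ser
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- 1 - exp(-xl) * (1 + xl + xl^2 / 2)
  }
  out
}

#' Damped electronic electric field at a probe point
#'
#' Sum over electrons of the damped Coulomb field
#' `E = sum_e f2(b r_e) (p - x_e) / r_e^3` (atomic units), smooth everywhere
#' including electron--probe coincidence, where the contribution vanishes.
#' Only electrons contribute: nuclear fields are configuration-independent
#' and cancel in the variance.
#'
#' @param electron_positions `n x 3` matrix (or length-3 vector) of electron
#'   positions, bohr.
#' @param probe length-3 probe point, bohr.
#' @param damping a [damping_spec()].
#' @return length-3 field vector, atomic units.
#' @export
damped_field <- function(electron_positions, probe, damping) {
  stopifnot(inherits(damping, "damping_spec"))
  if (is.null(dim(electron_positions)))
    electron_positions <- matrix(electron_positions, ncol = 3L)
  d <- -sweep(electron_positions, 2L, as.numeric(probe))  # probe - x_e
  r <- sqrt(rowSums(d * d))
  coef <- ifelse(r > 0, f2_damping(damping$b * r) / r^3, 0)
  colSums(d * coef)
}

# Fields for all snapshots of a sample at one probe: returns n x 3 matrix.
.field_batch <- function(snapshots, probe, b) {
  n <- dim(snapshots)[1L]; ne <- dim(snapshots)[2L]
  E <- matrix(0, n, 3L)
  for (e in seq_len(ne)) {
    D <- matrix(probe, n, 3L, byrow = TRUE) - snapshots[, e, ]
    r <- sqrt(rowSums(D * D))
    coef <- ifelse(r > 0, f2_damping(b * r) / r^3, 0)
    E <- E + D * coef
  }
  E
}

# Right-handed orthonormal triad with first axis along u.
.triad <- function(u) {
  L <- u / sqrt(sum(u^2))
  a <- c(0, 0, 0); a[which.min(abs(L))] <- 1
  T1 <- c(L[2] * a[3] - L[3] * a[2],
          L[3] * a[1] - L[1] * a[3],
          L[1] * a[2] - L[2] * a[1])
  T1 <- T1 / sqrt(sum(T1^2))
  T2 <- c(L[2] * T1[3] - L[3] * T1[2],
          L[3] * T1[1] - L[1] * T1[3],
          L[1] * T1[2] - L[2] * T1[1])
  rbind(L = L, T1 = T1, T2 = T2)
}

#' Monte Carlo field-fluctuation estimate at a probe point
#'
#' Computes the per-axis variances of the damped electronic electric field
#' over configuration snapshots in the longitudinal/transverse triad anchored
#' at the electronic center of charge, and their sum
#' `S^2 = sigma_L^2 + sigma_T1^2 + sigma_T2^2`.  The Monte Carlo standard
#' error of `S^2` is obtained from block means over the snapshot sequence.
#'
#' @param sample a [sample_configurations()] result.
#' @param probe length-3 probe point (bohr).
#' @param center_of_charge electronic center of charge (bohr) defining the
#'   longitudinal direction.
#' @param damping a [damping_spec()].
#' @param nblocks number of blocks for the standard-error estimate.
#' @return object of class `"fluctuation_probe"`: fields `point`, `axes`
#'   (rows L, T1, T2), `sigma2` (3 variances, a.u.), `s2`, `mc_error`,
#'   `mean_field`, `n`.
#' @export
field_variance <- function(sample, probe, center_of_charge, damping,
                           nblocks = 20L) {
  stopifnot(inherits(sample, "configuration_sample"))
  n <- sample$n_kept
  if (n < 2L) stop("need at least 2 snapshots to estimate a variance")
  E <- .field_batch(sample$snapshots, as.numeric(probe), damping$b)
  axes <- .triad(as.numeric(probe) - as.numeric(center_of_charge))
  Ep <- E %*% t(axes)                       # components in (L, T1, T2)
  mu <- colMeans(Ep)
  sigma2 <- colMeans(Ep^2) - mu^2
  s2 <- sum(sigma2)
  nb <- max(2L, min(as.integer(nblocks), n %/% 2L))
  blk <- cut(seq_len(n), nb, labels = FALSE)
  s2_blocks <- vapply(seq_len(nb), function(k) {
    Eb <- Ep[blk == k, , drop = FALSE]
    sum(colMeans(Eb^2) - colMeans(Eb)^2)
  }, numeric(1))
  mc_error <- stats::sd(s2_blocks) / sqrt(nb)
  structure(list(point = as.numeric(probe), axes = axes, sigma2 = sigma2,
                 s2 = s2, mc_error = mc_error,
                 mean_field = colMeans(E), n = n),
            class = "fluctuation_probe")
}

#' @export
print.fluctuation_probe <- function(x, ...) {
  cat(sprintf("S^2 = %.6e a.u. (MC error %.1e, n = %d)\n",
              x$s2, x$mc_error, x$n))
  cat(sprintf("  sigma^2 (L, T1, T2): %.3e %.3e %.3e\n",
              x$sigma2[1], x$sigma2[2], x$sigma2[3]))
  invisible(x)
}

## ---- quadrature oracle -----------------------------------------------------

# Radial rule {r, W} for an isotropic marginal with sum(W) = int r^2 rho dr
# = 1/(4 pi).
.oracle_radial_rule <- function(marg, n_r) {
  if (marg$kind == "gaussian") {
    gl <- pracma::gaussLegendre(n_r, 0, 12 * marg$sd)
    W <- gl$w * gl$x^2 * (2 * pi * marg$sd^2)^(-1.5) *
      exp(-gl$x^2 / (2 * marg$sd^2))
    list(r = gl$x, W = W)
  } else if (marg$kind == "hydrogenic") {
    lag <- pracma::gaussLaguerre(n_r, 2)
    list(r = lag$x / (2 * marg$Z), W = lag$w / (8 * pi))
  } else stop("no quadrature rule for marginal kind '", marg$kind, "'")
}

# Axial field moments of one isotropic marginal for probes at distances d
# (vector) from the marginal center: mean longitudinal field, second moments
# <Ez^2> and <Ex^2> (azimuthal integral analytic).  Vectorized over d.
.oracle_axial_moments <- function(marg, d, b, n_r = 120L, n_t = 80L) {
  rule <- .oracle_radial_rule(marg, n_r)
  tgl <- pracma::gaussLegendre(n_t, -1, 1)
  r <- rep(rule$r, each = n_t)
  t <- rep(tgl$x, times = n_r)
  w <- rep(rule$W, each = n_t) * rep(tgl$w, times = n_r)
  rt <- r * t
  rs <- r * sqrt(pmax(1 - t^2, 0))
  P <- length(d)
  mean_z <- Ez2 <- Ex2 <- numeric(P)
  chunk <- max(1L, floor(4e6 / length(r)))
  for (i0 in seq(1L, P, by = chunk)) {
    ii <- i0:min(P, i0 + chunk - 1L)
    dd <- d[ii]
    s2 <- outer(dd^2, r^2, "+") - 2 * outer(dd, rt)    # |probe - x|^2
    sz <- outer(dd, rt, "-")
    s <- sqrt(s2)
    kern <- f2_damping(b * s) / (s2 * s)
    kern[s2 == 0] <- 0
    gz <- kern * sz
    grho <- kern * rep(rs, each = length(dd))
    mean_z[ii] <- 2 * pi * as.numeric(gz %*% w)
    Ez2[ii] <- 2 * pi * as.numeric(gz^2 %*% w)
    Ex2[ii] <- pi * as.numeric(grho^2 %*% w)
  }
  list(mean_z = mean_z, Ez2 = Ez2, Ex2 = Ex2)
}

#' Deterministic field-fluctuation oracle for analytic model densities
#'
#' Brute-force quadrature evaluation of the damped-field fluctuation
#' `S^2(r)` for product wavefunctions with isotropic analytic marginals.
#' Exploits the axial symmetry of each marginal about its center--probe axis:
#' the azimuthal integral is analytic and the remaining radial x polar
#' quadrature uses Gauss--Legendre (Gaussian marginals) or Gauss--Laguerre
#' (hydrogen-like marginals) rules.  Independent of the Monte Carlo path.
#'
#' @param wf a [model_wavefunction()] with analytic marginals.
#' @param probe length-3 probe point (bohr).
#' @param damping a [damping_spec()].
#' @param n_r,n_t radial and polar quadrature orders.
#' @param components if `TRUE`, also return the directional variances in the
#'   (L, T1, T2) triad and the mean field.
#' @return `S^2` value (a.u.), or a `"fluctuation_probe"` object when
#'   `components = TRUE` (with `mc_error = 0`).
#' @export
s2_oracle <- function(wf, probe, damping, n_r = 120L, n_t = 80L,
                      components = FALSE) {
  stopifnot(inherits(wf, "model_wavefunction"),
            inherits(damping, "damping_spec"))
  if (!wf$has_analytic_marginals)
    stop("the quadrature oracle requires analytic marginals")
  probe <- as.numeric(probe)
  mean_tot <- c(0, 0, 0)
  cov_tot <- matrix(0, 3L, 3L)
  for (marg in wf$marginals) {
    u <- probe - marg$center
    d <- sqrt(sum(u^2))
    uhat <- if (d > 1e-12) u / d else c(0, 0, 1)
    if (marg$kind == "point") {
      mean_tot <- mean_tot + damped_field(marg$center, probe, damping)
      next
    }
    mom <- .oracle_axial_moments(marg, d, damping$b, n_r, n_t)
    sigL <- mom$Ez2 - mom$mean_z^2
    sigT <- mom$Ex2
    mean_tot <- mean_tot + mom$mean_z * uhat
    cov_tot <- cov_tot + sigT * (diag(3) - tcrossprod(uhat)) +
      sigL * tcrossprod(uhat)
  }
  s2 <- sum(diag(cov_tot))
  if (!components) return(s2)
  axes <- .triad(probe - wf$center_of_charge)
  sigma2 <- diag(axes %*% cov_tot %*% t(axes))
  structure(list(point = probe, axes = axes, sigma2 = sigma2, s2 = s2,
                 mc_error = 0, mean_field = mean_tot, n = Inf),
            class = "fluctuation_probe")
}

# Vectorized oracle over many probe points: returns the S^2 vector only.
# The trace of the field covariance is the sum of per-electron traces
# (independent electrons), so no triad bookkeeping is needed.
.s2_oracle_points <- function(wf, points, damping, n_r = 120L, n_t = 80L) {
  s2 <- numeric(nrow(points))
  for (marg in wf$marginals) {
    if (marg$kind == "point") next
    d <- sqrt(rowSums(sweep(points, 2L, marg$center)^2))
    mom <- .oracle_axial_moments(marg, d, damping$b, n_r, n_t)
    s2 <- s2 + (mom$Ez2 - mom$mean_z^2) + 2 * mom$Ex2
  }
  s2
}

# Monte Carlo S^2 at many probe points reusing one snapshot set; returns
# list(s2, mc_error) with block-mean standard errors per point.
.s2_mc_points <- function(sample, points, damping, nblocks = 16L) {
  n <- sample$n_kept
  nb <- max(2L, min(as.integer(nblocks), n %/% 2L))
  blk <- cut(seq_len(n), nb, labels = FALSE)
  P <- nrow(points)
  s2 <- mc <- numeric(P)
  b <- damping$b
  chunk <- max(1L, floor(2e6 / n))
  for (i0 in seq(1L, P, by = chunk)) {
    ii <- i0:min(P, i0 + chunk - 1L)
    for (j in seq_along(ii)) {
      E <- .field_batch(sample$snapshots, points[ii[j], ], b)
      mu <- colMeans(E)
      s2[ii[j]] <- sum(colMeans(E^2) - mu^2)
      s2b <- vapply(seq_len(nb), function(k) {
        Eb <- E[blk == k, , drop = FALSE]
        sum(colMeans(Eb^2) - colMeans(Eb)^2)
      }, numeric(1))
      mc[ii[j]] <- stats::sd(s2b) / sqrt(nb)
    }
  }
  list(s2 = s2, mc_error = mc)
}

#' Evaluate S^2 on a grid of probe points
#'
#' Builds a fluctuation grid from either the deterministic quadrature oracle
#' (analytic marginals) or a shared Monte Carlo snapshot set; all probes of a
#' Monte Carlo grid reuse one sample, so their errors are correlated.
#'
#' @param wf a [model_wavefunction()].
#' @param points `n x 3` matrix of probe points (bohr).
#' @param damping a [damping_spec()].
#' @param method `"auto"` (oracle when analytic marginals exist, else Monte
#'   Carlo), `"oracle"`, or `"mc"`.
#' @param sample a [sample_configurations()] result (required for
#'   `method = "mc"`).
#' @param ... passed to the oracle (`n_r`, `n_t`) or to the Monte Carlo
#'   evaluator (`nblocks`).
#' @return a data frame of class `"fluctuation_grid"` with columns `x`, `y`,
#'   `z`, `s2`, `mc_error` and a `provenance` attribute.
#' @export
fluctuation_grid <- function(wf, points, damping,
                             method = c("auto", "oracle", "mc"),
                             sample = NULL, ...) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point list")
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix")
  if (any(!is.finite(points))) stop("points must be finite")
  if (method == "auto")
    method <- if (!is.null(sample)) "mc"
      else if (wf$has_analytic_marginals) "oracle"
      else "mc"
  if (method == "oracle") {
    s2 <- .s2_oracle_points(wf, points, damping, ...)
    err <- rep(0, nrow(points))
    prov <- "quadrature-oracle"
  } else {
    if (is.null(sample)) stop("`sample` is required for the Monte Carlo path")
    res <- .s2_mc_points(sample, points, damping, ...)
    s2 <- res$s2; err <- res$mc_error
    prov <- sprintf("mc(n=%d, seed=%d)", sample$n_kept, sample$seed)
  }
  out <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                    s2 = s2, mc_error = err)
  attr(out, "provenance") <- prov
  class(out) <- c("fluctuation_grid", class(out))
  out
}

#' Export a fluctuation grid as tabular text
#'
#' Writes `x y z s2 err` columns, whitespace-separated, suitable for contour
#' plotting.
#'
#' @param grid a [fluctuation_grid()].
#' @param path output file.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid)[c("x", "y", "z", "s2", "mc_error")],
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
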