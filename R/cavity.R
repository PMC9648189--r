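# Molecule-shaped cavity of interlocking atomic spheres, solvent-dependent
# contact radii, scaling rules, membership tests and a converged quadrature
# over the cavity exterior.

.extdata <- function(name) {
  system.file("extdata", name, package = "dispersolv", mustWork = TRUE)
}

#' Packaged solute atomic radii
#'
#' Half-density atomic radii for the supported solute elements (bohr):
#' C 3.26, O 2.81, H 2.33.  Override rows or add elements by passing your own
#' data frame (`element`, `radius_bohr`) to [build_cavity()].
#'
#' @return data frame with columns `element`, `radius_bohr`.
#' @export
load_solute_radii <- function() {
  utils::read.delim(.extdata("solute_radii.tsv"), stringsAsFactors = FALSE)
}

#' Packaged solvent contact radii
#'
#' Per-solvent radii added to the solute atomic radius to form each cavity
#' sphere.  Hydrogen-bonding solvents (water, ethanol) present their hydrogen
#' (1.86 bohr) to solute oxygen; water presents its oxygen (2.96 bohr) to the
#' other solute atoms, ethanol a spherical CH3-group model (3.932 bohr).  The
#' remaining solvents use one sphere radius for all contacts.
#'
#' @return data frame with columns `name`, `contact_on_O`, `contact_elsewhere`
#'   (bohr).
#' @export
load_solvent_contacts <- function() {
  utils::read.delim(.extdata("solvent_contacts.tsv"), stringsAsFactors = FALSE)
}

#' Build the solvent-dependent interlocking-sphere cavity
#'
#' One sphere per solute atom, centered on its nucleus, with radius equal to
#' the solute atomic radius plus the solvent contact radius selected by the
#' contact rules (see [load_solvent_contacts()]).  A scale factor is applied
#' through [scale_cavity()], so the water exception (only solute-oxygen
#' spheres scale) is respected at construction too.
#'
#' @param atoms list of [atom()]s.
#' @param solvent_name solvent identifier present in the contacts table.
#' @param scale cavity scale factor (default 1).
#' @param solute_radii,solvent_contacts optional data frame overrides in the
#'   formats of [load_solute_radii()] and [load_solvent_contacts()].
#' @return object of class `"cavity"`.
#' @examples
#' hcho <- list(atom("C", c(0, 0, 0)), atom("O", c(0, 0, 2.28)),
#'              atom("H", c(1.78, 0, -1.1)), atom("H", c(-1.78, 0, -1.1)))
#' cav <- build_cavity(hcho, "water")
#' cav$spheres$radius   # 6.22 4.67 5.29 5.29
#' @export
build_cavity <- function(atoms, solvent_name, scale = 1,
                         solute_radii = NULL, solvent_contacts = NULL) {
  if (inherits(atoms, "atom")) atoms <- list(atoms)
  if (length(atoms) == 0L) stop("need at least one atom")
  if (is.null(solute_radii)) solute_radii <- load_solute_radii()
  if (is.null(solvent_contacts)) solvent_contacts <- load_solvent_contacts()
  row <- solvent_contacts[solvent_contacts$name == solvent_name, ]
  if (nrow(row) != 1L)
    stop("unknown solvent '", solvent_name,
         "'; supply `solvent_contacts` with contact radii")
  elements <- vapply(atoms, `[[`, character(1), "element")
  r_solute <- solute_radii$radius_bohr[match(elements, solute_radii$element)]
  if (any(is.na(r_solute)))
    stop("no solute radius for element(s): ",
         paste(unique(elements[is.na(r_solute)]), collapse = ", "),
         "; supply `solute_radii`")
  contact <- ifelse(elements == "O", row$contact_on_O, row$contact_elsewhere)
  centers <- t(vapply(atoms, `[[`, numeric(3), "position"))
  spheres <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        radius = r_solute + contact, element = elements,
                        stringsAsFactors = FALSE)
  cav <- structure(list(spheres = spheres, solvent_name = solvent_name,
                        scale = 1), class = "cavity")
  if (scale != 1) cav <- scale_cavity(cav, scale) else cav
}

#' Scale cavity radii
#'
#' Multiplies all sphere radii by `factor`, except for water as solvent,
#' where only the spheres centered on solute oxygen nuclei are scaled (the
#' hydrogen-bond contact spheres are held fixed).
#'
#' @param cavity a [build_cavity()] result.
#' @param factor positive scale factor.
#' @return the scaled cavity, with `scale` updated multiplicatively.
#' @export
scale_cavity <- function(cavity, factor) {
  stopifnot(inherits(cavity, "cavity"))
  if (!is.finite(factor) || factor <= 0) stop("`factor` must be > 0")
  sel <- if (cavity$solvent_name == "water")
    cavity$spheres$element == "O" else rep(TRUE, nrow(cavity$spheres))
  cavity$spheres$radius[sel] <- cavity$spheres$radius[sel] * factor
  cavity$scale <- cavity$scale * factor
  cavity
}

#' @export
print.cavity <- function(x, ...) {
  cat("Cavity:", nrow(x$spheres), "interlocking sphere(s), solvent",
      x$solvent_name, sprintf("(scale %.3f)\n", x$scale))
  print(x$spheres, digits = 4)
  invisible(x)
}

#' Cavity membership test
#'
#' A point is inside the cavity iff it lies in the strict interior of at
#' least one sphere; boundary points count as outside.
#'
#' @param cavity a [build_cavity()] result.
#' @param points length-3 vector or `n x 3` matrix (bohr).
#' @return logical vector.
#' @export
cavity_contains <- function(cavity, points) {
  stopifnot(inherits(cavity, "cavity"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  inside <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(cavity$spheres))) {
    ctr <- as.numeric(cavity$spheres[i, c("x", "y", "z")])
    d2 <- rowSums(sweep(points, 2L, ctr)^2)
    inside <- inside | d2 < cavity$spheres$radius[i]^2
  }
  inside
}

cavity_centroid <- function(cavity) {
  colMeans(as.matrix(cavity$spheres[, c("x", "y", "z")]))
}

#' Quadrature over the cavity exterior
#'
#' Product quadrature for integrals over the region outside the cavity:
#' angular directions (Gauss--Legendre in cos(theta) times a uniform
#' azimuthal grid) about the cavity centroid, and per-direction radial
#' Gauss--Legendre nodes on the ray segment from the cavity surface (the last
#' ray/sphere crossing) out to a truncation radius `r_max`.  The construction
#' assumes the sphere union is star-shaped about its centroid, which holds
#' for interlocking spheres; any stray interior node is masked out.  The
#' truncated tail beyond `r_max` is handled at integration time by
#' [quadrature_integrate()] under the verified `1/r^6` far-field decay of the
#' integrand.
#'
#' @param cavity a [build_cavity()] result.
#' @param radial_order,angular_order quadrature orders (>= 2).
#' @param r_max truncation radius (bohr); default `r_max_mult` times the
#'   largest centroid-to-sphere-surface distance.
#' @param r_max_mult multiplier for the default truncation radius.
#' @return object of class `"exterior_quadrature"`: `nodes` (`n x 3`),
#'   `weights` (bohr^3), `r_max`, `dirs`, `dir_weights` (solid angles,
#'   summing to 4 pi), `tail_nodes` (one point per direction at `r_max`).
#' @export
exterior_quadrature <- function(cavity, radial_order = 32L,
                                angular_order = 16L, r_max = NULL,
                                r_max_mult = 6) {
  stopifnot(inherits(cavity, "cavity"))
  if (nrow(cavity$spheres) == 0L) stop("cavity has no spheres")
  radial_order <- as.integer(radial_order)
  angular_order <- as.integer(angular_order)
  if (radial_order < 2L || angular_order < 2L) stop("orders must be >= 2")
  cen <- cavity_centroid(cavity)
  ang <- .angular_grid(angular_order)
  ndir <- nrow(ang$dirs)
  ctrs <- sweep(as.matrix(cavity$spheres[, c("x", "y", "z")]), 2L, cen)
  radii <- cavity$spheres$radius
  proj <- ang$dirs %*% t(ctrs)                         # ndir x nsph
  disc <- proj^2 - matrix(rowSums(ctrs^2), ndir, length(radii),
                          byrow = TRUE) + matrix(radii^2, ndir,
                                                 length(radii), byrow = TRUE)
  t_far <- ifelse(disc >= 0, proj + sqrt(pmax(disc, 0)), 0)
  r_exit <- pmax(apply(t_far, 1L, max), 0)
  reach <- max(sqrt(rowSums(ctrs^2)) + radii)
  if (is.null(r_max)) r_max <- r_max_mult * reach
  if (r_max <= max(r_exit))
    stop("`r_max` must exceed the cavity surface in every direction")
  gl <- pracma::gaussLegendre(radial_order, 0, 1)
  # per-direction affine map of [0,1] nodes onto [r_exit, r_max]
  half <- r_max - r_exit                              # ndir
  r <- outer(half, gl$x) + r_exit                     # ndir x nrad
  wr <- outer(half, gl$w) * r^2                       # radial weight * r^2
  nodes <- cbind(
    rep(ang$dirs[, 1], radial_order) * as.vector(r) + cen[1],
    rep(ang$dirs[, 2], radial_order) * as.vector(r) + cen[2],
    rep(ang$dirs[, 3], radial_order) * as.vector(r) + cen[3]
  )
  weights <- as.vector(wr) * rep(ang$w, radial_order)
  inside <- cavity_contains(cavity, nodes)
  if (any(inside)) {
    nodes <- nodes[!inside, , drop = FALSE]
    weights <- weights[!inside]
  }
  tail_nodes <- sweep(ang$dirs * r_max, 2L, cen, "+")
  structure(list(nodes = nodes, weights = weights, r_max = r_max,
                 dirs = ang$dirs, dir_weights = ang$w,
                 tail_nodes = tail_nodes, centroid = cen,
                 radial_order = radial_order, angular_order = angular_order),
            class = "exterior_quadrature")
}

#' @export
print.exterior_quadrature <- function(x, ...) {
  cat("Exterior quadrature:", nrow(x$nodes), "nodes,",
      sprintf("r_max = %.2f bohr\n", x$r_max))
  invisible(x)
}

#' Integrate a sampled function over the cavity exterior
#'
#' Computes `sum(w_i f_i)` plus, when tail values are supplied, the analytic
#' `1/r^6` tail correction beyond `r_max`: per direction the integrand is
#' extrapolated as `f(r_max) (r_max / r)^6`, whose exterior integral is
#' `f(r_max) r_max^3 / 3` per unit solid angle.
#'
#' @param quad an [exterior_quadrature()].
#' @param values integrand at `quad$nodes`.
#' @param tail_values integrand at `quad$tail_nodes` (optional).
#' @return list with `integral`, `tail`, `total`.
#' @export
quadrature_integrate <- function(quad, values, tail_values = NULL) {
  stopifnot(inherits(quad, "exterior_quadrature"),
            length(values) == nrow(quad$nodes))
  main <- sum(quad$weights * values)
  tail <- if (is.null(tail_values)) 0
    else sum(quad$dir_weights * tail_values) * quad$r_max^3 / 3
  list(integral = main, tail = tail, total = main + tail)
}

#' Export an exterior quadrature as tabular text
#'
#' Writes `x y z w` columns for audit.
#'
#' @param quad an [exterior_quadrature()].
#' @param path output file.
#' @export
write_quadrature <- function(quad, path) {
  utils::write.table(data.frame(x = quad$nodes[, 1], y = quad$nodes[, 2],
                                z = quad$nodes[, 3], w = quad$weights),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
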