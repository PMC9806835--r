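#' Molecular geometries as tibbles
#'
#' A molecular geometry is a tibble with one row per atom and columns
#' `element`, `mass` (u), `x`, `y`, `z` (Angstrom), carrying the total
#' charge (elementary charges) and a free-text label as attributes.
#' All geometry operations take such a tibble first and return one, so
#' they compose with the pipe.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge integer total charge; 0 for the neutral amino acids,
#'   +1 for their protonated forms.
#' @param label free-text identifier.
#' @param mass optional numeric vector of atomic masses in u; defaults to
#'   standard atomic weights looked up from `element`.
#' @return a `mol_geom` tibble.
#' @export
mol_geom <- function(element, xyz, charge = 0L, label = "", mass = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(length(element) >= 1L, ncol(xyz) == 3L,
            nrow(xyz) == length(element))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(mass)) mass <- atomic_mass(element)
  if (any(mass <= 0)) stop("atomic masses must be positive")
  out <- tibble::tibble(
    element = as.character(element),
    mass = as.numeric(mass),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  attr(out, "charge") <- as.integer(charge)
  attr(out, "label") <- label
  class(out) <- c("mol_geom", class(out))
  out
}

#' @rdname mol_geom
#' @param geometry a `mol_geom` tibble.
#' @export
geom_charge <- function(geometry) attr(geometry, "charge") %||% 0L

#' @rdname mol_geom
#' @export
geom_label <- function(geometry) attr(geometry, "label") %||% ""

# n x 3 coordinate matrix of a geometry
coords <- function(geometry) {
  cbind(geometry$x, geometry$y, geometry$z)
}

set_coords <- function(geometry, xyz) {
  geometry$x <- xyz[, 1]
  geometry$y <- xyz[, 2]
  geometry$z <- xyz[, 3]
  geometry
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure a dihedral angle
#'
#' Standard right-handed convention: the angle is positive when the far
#' bond `c-d` is rotated by the right-hand rule about the `b -> c` axis
#' relative to the near bond `b-a`. Angles are reported in (-180, 180]
#' degrees.
#'
#' @param geometry a `mol_geom` tibble.
#' @param atoms integer vector of four atom indices (a, b, c, d).
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(geometry, atoms) {
  stopifnot(length(atoms) == 4L)
  p <- coords(geometry)[atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  wrap_deg(ang)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# wrap angle(s) in degrees into (-180, 180]
wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

# Rodrigues rotation of row-vectors `xyz` about unit axis `u` through
# `origin` by `theta` radians (right-handed about u).
rotate_about_axis <- function(xyz, origin, u, theta) {
  v <- sweep(xyz, 2, origin)
  ct <- cos(theta); st <- sin(theta)
  dotp <- as.vector(v %*% u)
  vrot <- v * ct +
    t(vapply(seq_len(nrow(v)), function(i) cross3(u, v[i, ]), numeric(3))) * st +
    outer(dotp, u) * (1 - ct)
  sweep(vrot, 2, origin, `+`)
}

#' Rotate a torsion by a given angle
#'
#' Rotates the atoms in the torsion's moving set about its bond axis so
#' that the measured dihedral changes by exactly `angle` degrees. Atoms
#' outside the moving set are untouched, and all internal distances
#' within the moving set are preserved (rigid rotation).
#'
#' @param geometry a `mol_geom` tibble.
#' @param torsion a [torsion_spec()].
#' @param angle rotation in degrees; positive values increase the
#'   measured dihedral.
#' @return the rotated `mol_geom`.
#' @export
rotate_torsion <- function(geometry, torsion, angle) {
  ax <- torsion$axis
  mov <- torsion$moving_set
  n <- nrow(geometry)
  if (any(ax < 1L) || any(ax > n) || any(torsion$dihedral_atoms > n)) {
    stop("torsion atom indices out of range")
  }
  if (any(ax %in% mov)) stop("invalid torsion: axis atoms inside moving set")
  p <- coords(geometry)
  b <- p[ax[1], ]; c_ <- p[ax[2], ]
  u <- c_ - b
  len <- sqrt(sum(u^2))
  if (len < 1e-8) stop("degenerate geometry: zero-length torsion axis")
  u <- u / len
  # rotating the d-side by +angle about b->c (right-hand rule) increases
  # the measured dihedral by +angle; rotating the a-side decreases it
  da <- torsion$dihedral_atoms
  sense <- if (da[4] %in% mov) 1 else if (da[1] %in% mov) -1 else {
    stop("invalid torsion: moving set contains neither end of the dihedral")
  }
  p[mov, ] <- rotate_about_axis(p[mov, , drop = FALSE], b, u,
                                sense * angle * pi / 180)
  set_coords(geometry, p)
}

#' Rotational constants from principal moments of inertia
#'
#' Computes the moment-of-inertia tensor about the centre of mass,
#' diagonalises it, and converts the principal moments to rotational
#' constants A >= B >= C in cm^-1. Linear geometries (including all
#' diatomics) are flagged: the two finite constants are equal and A is
#' not defined.
#'
#' @param geometry a `mol_geom` tibble with at least two atoms.
#' @param linear_tol relative tolerance on the smallest principal moment
#'   for declaring the geometry linear.
#' @return a one-row tibble with columns `A`, `B`, `C` (cm^-1; `A` is
#'   `NA` for linear species) and `linear`.
#' @export
rotational_constants <- function(geometry, linear_tol = 1e-8) {
  if (nrow(geometry) < 2L) stop("need at least two atoms")
  m <- geometry$mass
  p <- coords(geometry)
  com <- colSums(p * m) / sum(m)
  p <- sweep(p, 2, com)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  I <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),       -sum(m * x * z),
    -sum(m * x * y),       sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),        sum(m * (x^2 + y^2))
  ), 3, 3)
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values) # u Angstrom^2
  k <- pa_constants
  # B[cm^-1] = h / (8 pi^2 c I), I in kg m^2
  conv <- k$h / (8 * pi^2 * k$c_cm * k$amu * 1e-20)
  linear <- ev[1] < linear_tol * max(ev[3], 1)
  if (linear) {
    Bc <- conv / ev[3] # I_b = I_c for a linear rotor
    tibble::tibble(A = NA_real_, B = Bc, C = conv / ev[2], linear = TRUE)
  } else {
    tibble::tibble(A = conv / ev[1], B = conv / ev[2], C = conv / ev[3],
                   linear = FALSE)
  }
}
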