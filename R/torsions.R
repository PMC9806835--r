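#' Define a rotatable torsion
#'
#' A torsion couples a rotation bond (the axis), a measured dihedral,
#' the set of atoms carried by the rotation, the grid step used during
#' enumeration and the local symmetry of the rotated group. A protonated
#' amino group (local C3v) has a 120 degree symmetry period, so a 60
#' degree grid visits only two distinct values; a `{C(OH)2}` group with
#' a local mirror lets the whole grid be halved once, which the
#' `mirror_equivalent` flag records.
#'
#' @param axis integer pair (b, c): the bond about which the rotation acts.
#' @param dihedral_atoms integer quadruple (a, b, c, d) defining the
#'   measured dihedral; its middle pair must equal `axis`.
#' @param moving_set integer indices of the atoms rotated with the bond;
#'   must exclude both axis atoms.
#' @param step_deg grid step in degrees; must divide 360.
#' @param symmetry_period_deg periodicity of the rotated group in degrees
#'   (360 for an asymmetric group, 120 for C3v); must divide 360 and be
#'   a multiple of `step_deg`.
#' @param mirror_equivalent logical; `TRUE` when a local mirror makes
#'   half the full grid redundant.
#' @param name optional label.
#' @return a `torsion_spec` object.
#' @export
torsion_spec <- function(axis, dihedral_atoms, moving_set,
                         step_deg = 60, symmetry_period_deg = 360,
                         mirror_equivalent = FALSE, name = NULL) {
  axis <- as.integer(axis)
  dihedral_atoms <- as.integer(dihedral_atoms)
  moving_set <- sort(unique(as.integer(moving_set)))
  stopifnot(length(axis) == 2L, length(dihedral_atoms) == 4L)
  if (!identical(dihedral_atoms[2:3], axis)) {
    stop("dihedral_atoms (a,b,c,d) must have (b,c) equal to the axis")
  }
  if (any(axis %in% moving_set)) {
    stop("moving_set must exclude the axis atoms")
  }
  if (360 %% step_deg != 0) stop("invalid grid: step must divide 360")
  if (360 %% symmetry_period_deg != 0) {
    stop("symmetry_period_deg must divide 360")
  }
  if (symmetry_period_deg %% step_deg != 0) {
    stop("invalid grid: step must divide the symmetry period")
  }
  structure(
    list(axis = axis, dihedral_atoms = dihedral_atoms,
         moving_set = moving_set, step_deg = step_deg,
         symmetry_period_deg = symmetry_period_deg,
         mirror_equivalent = isTRUE(mirror_equivalent),
         name = name %||% paste0("tor_", axis[1], "_", axis[2])),
    class = "torsion_spec"
  )
}

#' @export
print.torsion_spec <- function(x, ...) {
  cat(sprintf(
    "<torsion_spec %s: axis %d-%d, dihedral %s, %d moving atoms, step %g deg, period %g deg%s>\n",
    x$name, x$axis[1], x$axis[2],
    paste(x$dihedral_atoms, collapse = "-"),
    length(x$moving_set), x$step_deg, x$symmetry_period_deg,
    if (x$mirror_equivalent) ", mirror" else ""
  ))
  invisible(x)
}

#' Read torsion definitions from a YAML file
#'
#' The file holds a list of entries with fields `dihedral_atoms`,
#' `moving_set`, `step` (degrees), `symmetry_period` (degrees) and an
#' optional `mirror` flag and `name`; the axis is taken as the middle
#' pair of the dihedral. Indices are 1-based.
#'
#' @param path YAML file path.
#' @return a list of [torsion_spec()] objects.
#' @export
read_torsions <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- raw$torsions %||% raw
  purrr::map(entries, function(e) {
    da <- as.integer(e$dihedral_atoms)
    torsion_spec(
      axis = da[2:3],
      dihedral_atoms = da,
      moving_set = as.integer(e$moving_set),
      step_deg = e$step %||% 60,
      symmetry_period_deg = e$symmetry_period %||% 360,
      mirror_equivalent = isTRUE(e$mirror),
      name = e$name
    )
  })
}

#' Read and write XYZ files
#'
#' Standard two-header-line XYZ dialect: atom count, comment line, then
#' one `element x y z` row per atom in Angstrom. The comment line is
#' kept as the geometry label; a `charge=<n>` token inside it is parsed
#' back into the geometry's charge.
#'
#' @param path file path.
#' @return `read_xyz()` returns a `mol_geom`; `write_xyz()` returns the
#'   path invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 2 & !nzchar(trimws(lines)))]
  if (length(lines) < 3L) stop("malformed XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header: first line must be an atom count")
  comment <- lines[2]
  if (length(lines) < 2L + n) {
    stop("malformed XYZ file: header declares ", n, " atoms, found ",
         length(lines) - 2L)
  }
  body <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "\\s+"))
  if (ncol(body) < 4L) stop("malformed XYZ atom line")
  xyz <- matrix(as.numeric(body[, 2:4]), ncol = 3)
  if (anyNA(xyz)) stop("malformed XYZ coordinates")
  charge <- 0L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2L) charge <- as.integer(m[2])
  mol_geom(body[, 1], xyz, charge = charge, label = trimws(comment))
}

#' @rdname read_xyz
#' @param geometry a `mol_geom` tibble.
#' @param digits coordinate precision in the written file.
#' @export
write_xyz <- function(geometry, path, digits = 8) {
  lab <- geom_label(geometry)
  chg <- geom_charge(geometry)
  if (!grepl("charge=", lab) && chg != 0L) {
    lab <- trimws(paste(lab, sprintf("charge=%d", chg)))
  }
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  lines <- c(
    as.character(nrow(geometry)),
    lab,
    sprintf(fmt, geometry$element, geometry$x, geometry$y, geometry$z)
  )
  writeLines(lines, path)
  invisible(path)
}
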