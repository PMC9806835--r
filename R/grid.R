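#' Enumerate a symmetry-reduced torsional grid
#'
#' Each torsion contributes `symmetry_period_deg / step_deg` grid
#' values (0 and the period are the same structure), so five free
#' 60-degree rotations give 6^5 = 7776 starting points. A locally C3v
#' group (period 120) contributes only two values, and when any torsion
#' carries a `mirror_equivalent` flag the whole grid is halved once by
#' restricting that torsion to half its range.
#'
#' @param torsions a list of [torsion_spec()] objects (possibly empty:
#'   the grid then has the single seed point).
#' @return a `torsion_grid` with the closed-form point count; use
#'   [grid_points()] to materialise the angle tuples.
#' @export
enumerate_grid <- function(torsions) {
  if (inherits(torsions, "torsion_spec")) torsions <- list(torsions)
  stopifnot(all(vapply(torsions, inherits, logical(1), "torsion_spec")))
  counts <- vapply(torsions, function(t) {
    t$symmetry_period_deg / t$step_deg
  }, numeric(1))
  mirror_at <- which(vapply(torsions, function(t) t$mirror_equivalent,
                            logical(1)))
  n <- prod(counts)
  if (length(mirror_at)) n <- n / 2
  structure(
    list(torsions = torsions, counts = as.integer(counts),
         mirror_at = if (length(mirror_at)) mirror_at[1] else NA_integer_,
         n_points = as.integer(round(n))),
    class = "torsion_grid"
  )
}

#' @export
print.torsion_grid <- function(x, ...) {
  cat(sprintf("<torsion_grid: %d torsion(s), %d points%s>\n",
              length(x$torsions), x$n_points,
              if (!is.na(x$mirror_at)) " (mirror-halved)" else ""))
  invisible(x)
}

#' @rdname enumerate_grid
#' @param grid a `torsion_grid`.
#' @return `grid_points()` returns a tibble of angle tuples in degrees,
#'   one column per torsion, ordered lexicographically with the first
#'   torsion varying slowest.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "torsion_grid"))
  if (length(grid$torsions) == 0L) {
    return(tibble::tibble(.rows = 1L))
  }
  angles <- purrr::imap(grid$torsions, function(t, i) {
    period <- t$symmetry_period_deg
    if (!is.na(grid$mirror_at) && i == grid$mirror_at) period <- period / 2
    seq(0, period - t$step_deg, by = t$step_deg)
  })
  nm <- vapply(grid$torsions, function(t) t$name, character(1))
  names(angles) <- make.unique(nm, sep = "_")
  pts <- tidyr::expand_grid(!!!angles)
  stopifnot(nrow(pts) == grid$n_points)
  pts
}

#' Apply a grid point to a seed geometry
#'
#' Sets each torsion of the grid to the requested absolute dihedral by
#' rotating from the seed's current value.
#'
#' @param geometry seed `mol_geom`.
#' @param torsions list of [torsion_spec()]s.
#' @param angles numeric vector of target dihedrals in degrees, one per
#'   torsion.
#' @return the adjusted `mol_geom`.
#' @export
set_torsions <- function(geometry, torsions, angles) {
  stopifnot(length(torsions) == length(angles))
  for (i in seq_along(torsions)) {
    cur <- dihedral_angle(geometry, torsions[[i]]$dihedral_atoms)
    geometry <- rotate_torsion(geometry, torsions[[i]], angles[i] - cur)
  }
  geometry
}
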