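#' Drive a torsional grid search through an energy backend
#'
#' Optimises every grid start with the backend and records the outcome.
#' Non-convergence is data, not an error: failed starts are retained
#' with `converged = FALSE` and never abort the sweep. Converged
#' endpoints are assigned to conformers by clustering on final energy
#' and torus distance between angle tuples, and the per-conformer
#' occurrence tally counts how many starts funnelled into each.
#'
#' @param grid a [enumerate_grid()] result.
#' @param backend a backend with `optimize(point)` returning
#'   `list(par, value, converged)`, e.g. [toy_backend()].
#' @param e_tol energy tolerance (kcal/mol) for assigning two endpoints
#'   to the same conformer.
#' @param ang_tol maximum circular distance (degrees) between endpoint
#'   angle tuples assigned to the same conformer.
#' @return a `conformer_search` object: list with `records` (one row
#'   per start: start angles, `converged`, `energy`, final angles,
#'   `conformer`) and `conformers` (id, representative angles, `energy`,
#'   `relative_energy`, `occurrences`).
#' @export
run_search <- function(grid, backend, e_tol = 0.01, ang_tol = 15) {
  pts <- grid_points(grid)
  n_tor <- ncol(pts)
  recs <- purrr::map(seq_len(nrow(pts)), function(i) {
    start <- as.numeric(pts[i, ])
    res <- tryCatch(backend$optimize(start),
                    error = function(e) list(par = rep(NA_real_, n_tor),
                                             value = NA_real_,
                                             converged = FALSE))
    list(start = start, par = res$par, value = res$value,
         converged = isTRUE(res$converged))
  })
  records <- tibble::tibble(
    start = purrr::map(recs, "start"),
    final = purrr::map(recs, "par"),
    energy = purrr::map_dbl(recs, "value"),
    converged = purrr::map_lgl(recs, "converged")
  )

  # greedy assignment in order of increasing energy: a converged record
  # joins the first conformer within both tolerances, else founds a new one
  conf_angles <- list()
  conf_energy <- numeric(0)
  assignment <- rep(NA_integer_, nrow(records))
  ord <- order(records$energy, na.last = TRUE)
  for (i in ord) {
    if (!records$converged[i]) next
    hit <- NA_integer_
    for (k in seq_along(conf_angles)) {
      if (abs(records$energy[i] - conf_energy[k]) < e_tol &&
          torus_distance(records$final[[i]], conf_angles[[k]]) < ang_tol) {
        hit <- k
        break
      }
    }
    if (is.na(hit)) {
      conf_angles[[length(conf_angles) + 1L]] <- records$final[[i]]
      conf_energy <- c(conf_energy, records$energy[i])
      hit <- length(conf_angles)
    }
    assignment[i] <- hit
  }
  records$conformer <- assignment

  conformers <- tibble::tibble(
    id = seq_along(conf_angles),
    angles = conf_angles,
    energy = conf_energy,
    occurrences = vapply(seq_along(conf_angles),
                         function(k) sum(assignment == k, na.rm = TRUE),
                         integer(1))
  ) |>
    dplyr::arrange(.data$energy) |>
    dplyr::mutate(id = dplyr::row_number(),
                  relative_energy = .data$energy - min(.data$energy))

  structure(list(records = records, conformers = conformers,
                 grid = grid, e_tol = e_tol, ang_tol = ang_tol),
            class = "conformer_search")
}

#' @export
print.conformer_search <- function(x, ...) {
  cat(sprintf(
    "<conformer_search: %d starts, %d converged, %d conformer(s)>\n",
    nrow(x$records), sum(x$records$converged), nrow(x$conformers)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conformer_search <- function(x, ...) x$conformers

#' @exportS3Method generics::glance
glance.conformer_search <- function(x, ...) {
  tibble::tibble(
    n_starts = nrow(x$records),
    n_converged = sum(x$records$converged),
    n_conformers = nrow(x$conformers),
    min_energy = min(x$conformers$energy)
  )
}

#' Deduplicate conformer entries by relative energy and A constant
#'
#' Two entries are the same structure only when both fingerprints
#' agree: the relative-energy difference is below `e_tol` and the
#' A-rotational-constant difference is within `a_tol`. Anything else is
#' a different conformer. Merging is the transitive closure of that
#' relation (hand-rolled union-find); each cluster is represented by
#' its lowest-energy member. Relative energies are taken against the
#' current set minimum and the pass is repeated on the representatives
#' until a fixed point, so the operation is idempotent.
#'
#' @param entries tibble with columns `energy` (kcal/mol, absolute or
#'   already-relative) and `A` (cm^-1); other columns are carried
#'   through from the representative row.
#' @param e_tol minimum relative-energy difference (kcal/mol) declaring
#'   two structures different; default 0.01.
#' @param a_tol maximum A-constant deviation (cm^-1) still considered
#'   equal; default 3e-4.
#' @return the clustered tibble, sorted by relative energy, with
#'   `relative_energy` and `cluster_size` columns.
#' @export
deduplicate <- function(entries, e_tol = 0.01, a_tol = 3e-4) {
  stopifnot(e_tol > 0, a_tol > 0,
            all(c("energy", "A") %in% names(entries)))
  current <- entries
  repeat {
    merged <- dedup_pass(current, e_tol, a_tol)
    if (nrow(merged) == nrow(current)) break
    current <- merged
  }
  merged |>
    dplyr::arrange(.data$relative_energy)
}

dedup_pass <- function(entries, e_tol, a_tol) {
  n <- nrow(entries)
  rel <- entries$energy - min(entries$energy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (abs(rel[i] - rel[j]) < e_tol &&
            abs(entries$A[i] - entries$A[j]) <= a_tol) {
          unite(i, j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  entries |>
    dplyr::mutate(.cluster = root, .rel = rel) |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::mutate(.size = dplyr::n()) |>
    dplyr::slice_min(.data$energy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(relative_energy = .data$energy - min(.data$energy),
                  cluster_size = .data$.size) |>
    dplyr::select(-".cluster", -".rel", -".size")
}

#' Keep only true minima
#'
#' Stationary points from the grid sweep include transition states;
#' once harmonic frequencies are available, a minimum is exactly an
#' entry with no imaginary mode. Entries whose imaginary count has not
#' been evaluated are an error — they are never silently kept.
#'
#' @param entries tibble with an `n_imaginary` integer column.
#' @return the rows with `n_imaginary == 0`.
#' @export
filter_minima <- function(entries) {
  if (!"n_imaginary" %in% names(entries)) {
    stop("entries lack an n_imaginary column")
  }
  if (anyNA(entries$n_imaginary)) {
    stop("unevaluated entries: n_imaginary missing for ",
         sum(is.na(entries$n_imaginary)), " row(s)")
  }
  dplyr::filter(entries, .data$n_imaginary == 0L)
}
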