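#' Analytic torsional toy potential
#'
#' A smooth, 2-pi-periodic multi-well energy surface over a set of
#' torsion angles,
#' `V(phi) = sum_j sum_k a[j,k] (1 - cos(k phi_j - delta[j,k]))
#'  + sum_{i<j} c[i,j] (1 - cos(phi_i - phi_j))`,
#' in kcal/mol with angles in degrees at the interface. It emulates the
#' funnelling behaviour of a real conformational landscape — many grid
#' starts drain into few minima — while every property (energy,
#' gradient, Hessian, the complete minimum catalogue) is available in
#' closed form or by dense scanning, so the search machinery can be
#' validated exactly. It is a workflow test double, not a model of any
#' real molecule.
#'
#' @param amplitudes numeric matrix (n_torsions x K) of Fourier
#'   amplitudes `a[j,k]` in kcal/mol.
#' @param phases matrix like `amplitudes` holding the offsets
#'   `delta[j,k]` in degrees.
#' @param coupling optional symmetric matrix (n x n) of pairwise
#'   coupling amplitudes in kcal/mol; diagonal ignored.
#' @return a `toy_pes` object.
#' @export
toy_pes <- function(amplitudes, phases = NULL, coupling = NULL) {
  amplitudes <- rbind(amplitudes)
  if (is.null(phases)) phases <- matrix(0, nrow(amplitudes), ncol(amplitudes))
  phases <- rbind(phases)
  stopifnot(identical(dim(amplitudes), dim(phases)))
  n <- nrow(amplitudes)
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  stopifnot(nrow(coupling) == n, ncol(coupling) == n)
  structure(list(amplitudes = amplitudes, phases = phases,
                 coupling = coupling, n_torsions = n),
            class = "toy_pes")
}

#' @rdname toy_pes
#' @param point numeric vector of torsion angles in degrees.
#' @param pes a `toy_pes`.
#' @return `toy_energy()` returns the potential in kcal/mol.
#' @export
toy_energy <- function(point, pes) {
  stopifnot(inherits(pes, "toy_pes"))
  if (length(point) != pes$n_torsions) {
    stop("point dimension (", length(point),
         ") does not match the potential (", pes$n_torsions, ")")
  }
  phi <- point * pi / 180
  del <- pes$phases * pi / 180
  v <- 0
  for (j in seq_len(pes$n_torsions)) {
    for (k in seq_len(ncol(pes$amplitudes))) {
      v <- v + pes$amplitudes[j, k] * (1 - cos(k * phi[j] - del[j, k]))
    }
  }
  if (pes$n_torsions > 1L) {
    for (i in seq_len(pes$n_torsions - 1L)) {
      for (j in (i + 1L):pes$n_torsions) {
        v <- v + pes$coupling[i, j] * (1 - cos(phi[i] - phi[j]))
      }
    }
  }
  v
}

# analytic gradient in kcal/mol per radian
toy_gradient <- function(point, pes) {
  phi <- point * pi / 180
  del <- pes$phases * pi / 180
  g <- numeric(pes$n_torsions)
  for (j in seq_len(pes$n_torsions)) {
    for (k in seq_len(ncol(pes$amplitudes))) {
      g[j] <- g[j] + pes$amplitudes[j, k] * k * sin(k * phi[j] - del[j, k])
    }
  }
  if (pes$n_torsions > 1L) {
    for (i in seq_len(pes$n_torsions - 1L)) {
      for (j in (i + 1L):pes$n_torsions) {
        s <- pes$coupling[i, j] * sin(phi[i] - phi[j])
        g[i] <- g[i] + s
        g[j] <- g[j] - s
      }
    }
  }
  g
}

#' Energy backend over the toy potential
#'
#' Packages the toy surface behind the backend contract the search
#' driver expects: `energy(point)`, `optimize(point)` and
#' `frequencies(point)`, all in torsion space (angles in degrees).
#' Optimisation is quasi-Newton (BFGS with the analytic gradient) run
#' to a gradient norm below `grad_tol`; it is idempotent at a converged
#' point. Frequencies come from a central-difference Hessian in torsion
#' coordinates (step 0.5 degrees) whose eigenvalues are mapped to
#' nominal wavenumbers by a fixed scale — imaginary modes are encoded
#' as negative numbers. These wavenumbers order stationary points
#' correctly but are not physical vibrational frequencies.
#'
#' @param pes a [toy_pes()].
#' @param grad_tol convergence threshold on the max absolute gradient
#'   component, kcal/mol per radian.
#' @param freq_scale nominal cm^-1 per sqrt(kcal/mol)/rad curvature unit.
#' @return a `list(energy, optimize, frequencies, n_torsions)` backend.
#' @export
toy_backend <- function(pes, grad_tol = 1e-6, freq_scale = 500) {
  stopifnot(inherits(pes, "toy_pes"))
  energy <- function(point) toy_energy(point, pes)
  optimize <- function(point) {
    fn <- function(phi_rad) toy_energy(phi_rad * 180 / pi, pes)
    gr <- function(phi_rad) toy_gradient(phi_rad * 180 / pi, pes)
    res <- stats::optim(point * pi / 180, fn, gr, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    par_deg <- wrap_deg(res$par * 180 / pi)
    gmax <- max(abs(toy_gradient(par_deg, pes)))
    list(par = par_deg, value = res$value,
         converged = res$convergence == 0L && gmax < grad_tol)
  }
  frequencies <- function(point) {
    H <- toy_hessian(point, pes, step_deg = 0.5)
    lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    sign(lam) * sqrt(abs(lam)) * freq_scale
  }
  list(energy = energy, optimize = optimize, frequencies = frequencies,
       n_torsions = pes$n_torsions)
}

# central-difference Hessian in kcal/mol per rad^2
toy_hessian <- function(point, pes, step_deg = 0.5) {
  n <- pes$n_torsions
  h <- step_deg
  H <- matrix(0, n, n)
  f0 <- toy_energy(point, pes)
  shift <- function(i, s) { p <- point; p[i] <- p[i] + s; p }
  for (i in seq_len(n)) {
    H[i, i] <- (toy_energy(shift(i, h), pes) - 2 * f0 +
                  toy_energy(shift(i, -h), pes))
    if (i < n) for (j in (i + 1L):n) {
      shift2 <- function(si, sj) {
        p <- point; p[i] <- p[i] + si; p[j] <- p[j] + sj; p
      }
      H[i, j] <- H[j, i] <- (toy_energy(shift2(h, h), pes) -
                               toy_energy(shift2(h, -h), pes) -
                               toy_energy(shift2(-h, h), pes) +
                               toy_energy(shift2(-h, -h), pes)) / 4
    }
  }
  H / (h * pi / 180)^2
}

#' Catalogue the minima of a toy potential by dense scanning
#'
#' Exhaustively evaluates the surface on a fine grid and keeps points
#' lower than all torus neighbours, then polishes each with the backend
#' optimiser. Serves as the independent oracle against which grid
#' searches are validated; practical up to two or three torsions.
#'
#' @param pes a [toy_pes()].
#' @param resolution_deg scan resolution in degrees (default 1).
#' @return tibble of distinct minima: angle columns plus `energy`.
#' @export
toy_minima_scan <- function(pes, resolution_deg = 1) {
  n <- pes$n_torsions
  ax <- seq(0, 360 - resolution_deg, by = resolution_deg)
  grid <- as.matrix(do.call(tidyr::expand_grid,
                            stats::setNames(rep(list(ax), n),
                                            paste0("phi", seq_len(n)))))
  vals <- apply(grid, 1, toy_energy, pes = pes)
  dim_sizes <- rep(length(ax), n)
  is_min <- rep(TRUE, length(vals))
  # compare against the 2n axis neighbours on the torus
  idx <- arrayInd(seq_along(vals), .dim = rev(dim_sizes))
  for (d in seq_len(n)) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, n - d + 1L] <- ((nb[, n - d + 1L] - 1L + s) %% length(ax)) + 1L
      nb_lin <- nb[, 1]
      if (n > 1L) for (k in 2:n) {
        nb_lin <- nb_lin + (nb[, k] - 1L) * prod(rev(dim_sizes)[1:(k - 1L)])
      }
      is_min <- is_min & vals <= vals[nb_lin]
    }
  }
  cand <- grid[is_min, , drop = FALSE]
  bk <- toy_backend(pes)
  polished <- purrr::map(seq_len(nrow(cand)),
                         function(i) bk$optimize(cand[i, ]))
  pts <- do.call(rbind, purrr::map(polished, "par"))
  en <- vapply(polished, function(r) r$value, numeric(1))
  out <- tibble::as_tibble(as.data.frame(pts))
  names(out) <- paste0("phi", seq_len(n))
  out$energy <- en
  dedupe_torus_points(out, n, ang_tol = 1)
}

# collapse scan hits that polished into the same minimum
dedupe_torus_points <- function(df, n, ang_tol = 1) {
  keep <- integer(0)
  for (i in order(df$energy)) {
    dup <- FALSE
    for (k in keep) {
      d <- torus_distance(as.numeric(df[i, 1:n]), as.numeric(df[k, 1:n]))
      if (d < ang_tol && abs(df$energy[i] - df$energy[k]) < 1e-6) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  dplyr::arrange(df[sort(keep), , drop = FALSE], .data$energy)
}

# max circular distance (degrees) between two angle tuples
torus_distance <- function(a, b) {
  d <- abs(wrap_deg(a - b))
  max(d)
}
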