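#' Boltzmann conformer populations
#'
#' `x_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)` over the relative
#' standard Gibbs free energies of the conformers. Populations sum to
#' one, every population is positive, and adding a constant to all
#' free energies leaves them unchanged (gauge invariance).
#'
#' @param dG_rel numeric vector of relative Gibbs free energies in
#'   kcal/mol (the most stable conformer at 0).
#' @param temperature K, > 0.
#' @param id optional conformer labels.
#' @return a `population_set` tibble with `id`, `dG_rel`, `x`.
#' @export
boltzmann_populations <- function(dG_rel, temperature = 298.15, id = NULL) {
  if (length(dG_rel) == 0L) stop("empty free-energy input")
  if (temperature <= 0) stop("temperature must be positive")
  if (any(!is.finite(dG_rel))) stop("non-finite free energies")
  RT <- pa_constants$R_kcal * temperature
  w <- exp(-(dG_rel - min(dG_rel)) / RT)
  out <- tibble::tibble(
    id = id %||% as.character(utils::as.roman(seq_along(dG_rel))),
    dG_rel = dG_rel,
    x = w / sum(w)
  )
  attr(out, "temperature") <- temperature
  class(out) <- c("population_set", class(out))
  out
}

#' Population-weighted mixture enthalpy
#'
#' `sum_i x_i H_i` over aligned populations and per-conformer relative
#' enthalpies.
#'
#' @param populations a [boltzmann_populations()] result.
#' @param H_rel numeric vector of relative enthalpies (kcal/mol)
#'   aligned with the populations.
#' @return the weighted mean in kcal/mol.
#' @export
mixture_enthalpy <- function(populations, H_rel) {
  if (length(H_rel) != nrow(populations)) {
    stop("misaligned inputs: ", nrow(populations), " populations vs ",
         length(H_rel), " enthalpies")
  }
  sum(populations$x * H_rel)
}

#' Ensemble mixture free energy
#'
#' The free energy of an equilibrium conformer ensemble,
#' `G_mix = -RT ln sum_i exp(-G_i / RT)`, which includes the
#' configurational (mixing) contribution; algebraically it equals
#' `sum x_i G_i + RT sum x_i ln x_i` and is therefore never above the
#' population-weighted mean.
#'
#' @param G_rel numeric vector of relative Gibbs free energies in
#'   kcal/mol.
#' @param temperature K.
#' @return ensemble free energy in kcal/mol (relative to the same
#'   reference as the input).
#' @export
mixture_free_energy <- function(G_rel, temperature = 298.15) {
  if (length(G_rel) == 0L) stop("empty free-energy input")
  if (temperature <= 0) stop("temperature must be positive")
  RT <- pa_constants$R_kcal * temperature
  off <- min(G_rel)
  off - RT * log(sum(exp(-(G_rel - off) / RT)))
}

#' Site-resolved mixture proton affinity and gas-phase basicity
#'
#' Combines the lowest-conformer anchor values with Boltzmann-mixture
#' shifts from the two species' conformer tables. Populations are
#' computed once per species from the 298.15 K relative free-energy
#' column and reused for every averaged quantity (including the 0 K
#' enthalpies):
#'
#' * mixture PA (per temperature) = anchor PA
#'   + \<dH\>_neutral - \<dH\>_protonated (population-weighted means);
#' * mixture GB = anchor GB + G_mix(neutral) - G_mix(protonated) with
#'   the ensemble free energy of [mixture_free_energy()].
#'
#' With a single conformer on each side (or all conformers degenerate
#' with the anchor) every shift vanishes and the anchor values are
#' returned unchanged.
#'
#' @param neutral,protonated tibbles with relative thermal columns
#'   `d_h0`, `d_h298`, `d_g298` (kcal/mol, conformer I at 0), e.g. the
#'   packaged benchmark tables or [assemble_benchmark()] output joined
#'   with thermal data.
#' @param anchor named list or vector with the lowest-conformer
#'   `pa_0k`, `pa_298k`, `gb_298k` values in kcal/mol.
#' @param temperature K for populations and mixing terms.
#' @param site optional site label (`"N"`, `"O"`, `"S"`, ...).
#' @return a `site_pa_gb` tibble with one row per flavor
#'   (`lowest-conformer`, `mixture`) and columns `site`, `flavor`,
#'   `pa_0k`, `pa_298k`, `gb_298k`.
#' @export
site_pa_gb <- function(neutral, protonated, anchor,
                       temperature = 298.15, site = NA_character_) {
  anchor <- as.list(anchor)
  need <- c("pa_0k", "pa_298k", "gb_298k")
  if (!all(need %in% names(anchor))) {
    stop("anchor must provide ", paste(need, collapse = ", "))
  }
  for (tab in list(neutral, protonated)) {
    require_columns(tab, c("d_h0", "d_h298", "d_g298"), "mixture PA/GB")
  }
  pop_n <- boltzmann_populations(neutral$d_g298, temperature)
  pop_p <- boltzmann_populations(protonated$d_g298, temperature)

  d_pa0 <- mixture_enthalpy(pop_n, neutral$d_h0) -
    mixture_enthalpy(pop_p, protonated$d_h0)
  d_pa298 <- mixture_enthalpy(pop_n, neutral$d_h298) -
    mixture_enthalpy(pop_p, protonated$d_h298)
  d_gb <- mixture_free_energy(neutral$d_g298, temperature) -
    mixture_free_energy(protonated$d_g298, temperature)

  out <- tibble::tibble(
    site = site,
    flavor = c("lowest-conformer", "mixture"),
    pa_0k = c(anchor$pa_0k, anchor$pa_0k + d_pa0),
    pa_298k = c(anchor$pa_298k, anchor$pa_298k + d_pa298),
    gb_298k = c(anchor$gb_298k, anchor$gb_298k + d_gb)
  )
  attr(out, "temperature") <- temperature
  attr(out, "populations") <- list(neutral = pop_n, protonated = pop_p)
  class(out) <- c("site_pa_gb", class(out))
  out
}

#' @exportS3Method generics::glance
glance.site_pa_gb <- function(x, ...) {
  mix <- dplyr::filter(x, .data$flavor == "mixture")
  tibble::tibble(
    site = mix$site,
    pa_298k = mix$pa_298k,
    gb_298k = mix$gb_298k,
    entropy_lowering = mix$pa_298k - mix$gb_298k,
    temperature = attr(x, "temperature")
  )
}

#' @exportS3Method generics::tidy
tidy.site_pa_gb <- function(x, ...) {
  tibble::as_tibble(x)
}
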