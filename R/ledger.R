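#' Energy ledgers
#'
#' A ledger is a tibble with one row per conformer holding the
#' single-point energies and auxiliary corrections from which the
#' focal-point composite energy is assembled. All energy columns are
#' kcal/mol. A ledger is either *relative* (values referenced to the
#' first conformer, which sits at zero in every energy column — the
#' form in which benchmark tables are printed) or *absolute*; the
#' `values` attribute disambiguates. Raw ledgers carry the column pairs
#' the corrections are computed from; derived ledgers carry the
#' corrections themselves:
#'
#' * raw: `e_qz_f12b`, `e_ae_cvtz`/`e_fc_cvtz` (core correlation),
#'   `e_dk`/`e_nodk` (scalar relativity), `e_ccsd_t_631g`/
#'   `e_ccsdt_631g`/`e_ccsdt_q_631g` (post-(T)), `zpe`; optionally
#'   `e_cc_dz_mp2geom`/`e_cc_dz` for the geometry effect.
#' * derived: `e_qz_f12b`, `d_core`, `d_rel`, `d_t`, `d_q`, `d_zpe`
#'   (plus any thermal columns `d_h0`, `d_h298`, `d_g298`).
#'
#' @param x a data frame of ledger columns.
#' @param values `"relative"` or `"absolute"`. Absolute ledgers given
#'   in hartree (`units = "hartree"`) are converted to kcal/mol on
#'   ingest.
#' @param units `"kcal/mol"` (default) or `"hartree"`.
#' @return a tibble with the `values` attribute set.
#' @export
energy_ledger <- function(x, values = c("relative", "absolute"),
                          units = c("kcal/mol", "hartree")) {
  values <- match.arg(values)
  units <- match.arg(units)
  x <- tibble::as_tibble(x)
  ecols <- ledger_energy_columns(x)
  if (units == "hartree") {
    x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(ecols),
                                        ~ .x * pa_constants$kcal_per_hartree))
  }
  if (values == "relative" && nrow(x) > 0) {
    first <- as.numeric(x[1, ecols])
    if (any(abs(first) > 1e-9)) {
      stop("relative ledger must have its first conformer at zero in ",
           "every energy column")
    }
  }
  attr(x, "values") <- values
  x
}

ledger_energy_columns <- function(x) {
  known <- c("e_mp2", "e_cc_dz_mp2geom", "e_cc_dz", "e_cc_tz",
             "e_qz_f12a", "e_qz_f12b", "e_ae_cvtz", "e_fc_cvtz",
             "e_dk", "e_nodk", "e_ccsd_t_631g", "e_ccsdt_631g",
             "e_ccsdt_q_631g", "zpe", "d_core", "d_rel", "d_t", "d_q",
             "d_e_e", "d_zpe", "d_h0", "d_h298", "d_g298")
  intersect(known, names(x))
}

ledger_values <- function(ledger) attr(ledger, "values") %||% "relative"

require_columns <- function(ledger, cols, what) {
  missing <- setdiff(cols, names(ledger))
  if (length(missing)) {
    stop("missing ledger column(s) for ", what, ": ",
         paste(missing, collapse = ", "))
  }
  invisible(ledger)
}

#' Generate a synthetic correction ledger
#'
#' Emulates the magnitude structure of published focal-point benchmark
#' tables: relative energies spread over a few kcal/mol, auxiliary
#' corrections of order 0.01-0.1 kcal/mol, and ZPE corrections whose
#' mean and sign depend on the protonation site (near zero with varying
#' sign for N-protonation, negative for O-protonation, clearly positive
#' for S-protonation). The output is a *raw* relative ledger — the
#' correction columns come out of [assemble_benchmark()], exercising
#' the same code path as real data. Reproducible under a fixed seed.
#'
#' @param n_conformers number of conformers (first one is the
#'   reference, all-zero row).
#' @param site `"neutral"`, `"N"`, `"O"` or `"S"`; sets the ZPE
#'   correction regime.
#' @param energy_range span of relative energies in kcal/mol.
#' @param core_scale,rel_scale,post_t_scale standard deviations
#'   (kcal/mol) of the core, relativistic and post-(T) correction
#'   columns.
#' @param zpe_mean,zpe_sd mean and spread of the ZPE correction; the
#'   default mean is site-dependent (0 for `neutral`/`N`, -0.47 for
#'   `O`, +0.79 for `S`, the published per-site averages).
#' @param seed integer random seed, recorded in the `seed` attribute.
#' @return a raw relative ledger tibble.
#' @export
generate_ledger <- function(n_conformers = 10, site = c("neutral", "N", "O", "S"),
                            energy_range = c(0, 8),
                            core_scale = 0.03, rel_scale = 0.01,
                            post_t_scale = 0.03,
                            zpe_mean = NULL, zpe_sd = 0.15,
                            seed = 1L) {
  site <- match.arg(site)
  stopifnot(n_conformers >= 1, diff(energy_range) >= 0,
            core_scale >= 0, rel_scale >= 0, post_t_scale >= 0, zpe_sd >= 0)
  if (is.null(zpe_mean)) {
    zpe_mean <- switch(site, neutral = 0, N = 0, O = -0.47, S = 0.79)
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    n <- n_conformers
    base <- c(0, sort(stats::runif(n - 1, energy_range[1], energy_range[2])))
    jig <- function(scale) c(0, stats::rnorm(n - 1, 0, scale))
    d_core <- jig(core_scale)
    d_rel <- jig(rel_scale)
    d_t <- jig(post_t_scale / 2)
    d_q <- jig(post_t_scale)
    zpe <- c(0, zpe_mean + stats::rnorm(n - 1, 0, zpe_sd))
    led <- tibble::tibble(
      name = as.character(utils::as.roman(seq_len(n))),
      e_qz_f12b = base,
      e_ae_cvtz = base + d_core, e_fc_cvtz = base,
      e_dk = base + d_rel, e_nodk = base,
      e_ccsd_t_631g = base,
      e_ccsdt_631g = base + d_t,
      e_ccsdt_q_631g = base + d_t + d_q,
      e_cc_dz = base + jig(0.02),
      e_cc_dz_mp2geom = base + jig(0.02),
      zpe = zpe
    )
    out <- energy_ledger(led, values = "relative")
    attr(out, "seed") <- seed
    attr(out, "site") <- site
    out
  })
}
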