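#' Read an energy ledger from CSV
#'
#' The schema mirrors the benchmark tables: one row per conformer,
#' energy columns in kcal/mol, leading `#` comment lines carrying the
#' units. Unknown columns are preserved untouched.
#'
#' @param path CSV file path.
#' @param values `"relative"` (default; conformer I at zero) or
#'   `"absolute"`.
#' @param units `"kcal/mol"` or `"hartree"` (absolute ledgers only).
#' @return an [energy_ledger()] tibble.
#' @export
read_ledger <- function(path, values = "relative", units = "kcal/mol") {
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                          check.names = FALSE))
  if (nrow(df) == 0L) stop("empty ledger file: ", path)
  energy_ledger(df, values = values, units = units)
}

#' Write a results table to CSV
#'
#' Writes with a units comment header so that a round trip through
#' [read_ledger()] (or `readr::read_csv(comment = "#")`) reproduces
#' the values exactly (full double precision).
#'
#' @param results a data frame.
#' @param path output path.
#' @param comment header comment (written after `# `).
#' @return the path, invisibly.
#' @export
write_report <- function(results, path,
                         comment = "units: kcal/mol (energy columns)") {
  out <- as.data.frame(results)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  lines <- c(paste("#", comment),
             paste(names(out), collapse = ","),
             do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged cysteine benchmark tables
#'
#' Transcriptions of the published per-conformer benchmark tables for
#' the 10 lowest-lying conformers of neutral, N-, O- and S-protonated
#' cysteine (relative energies, focal-point corrections, ZPE, and
#' relative H/G at 0 and 298.15 K; all kcal/mol, relative to conformer
#' I of each species), plus the site-resolved proton affinity /
#' gas-phase basicity summary.
#'
#' @param species `"neutral"`, `"N"`, `"O"` or `"S"`.
#' @return `cysteine_benchmark_table()`: a relative [energy_ledger()];
#'   `cysteine_pa_table()`: an absolute tibble with one row per
#'   (site, flavor) pair.
#' @export
cysteine_benchmark_table <- function(species = c("neutral", "N", "O", "S")) {
  species <- match.arg(species)
  fname <- switch(species,
                  neutral = "cysteine_neutral_benchmark.csv",
                  N = "cysteine_Nprot_benchmark.csv",
                  O = "cysteine_Oprot_benchmark.csv",
                  S = "cysteine_Sprot_benchmark.csv")
  read_ledger(pkg_extdata(fname), values = "relative")
}

#' @rdname cysteine_benchmark_table
#' @export
cysteine_pa_table <- function() {
  df <- readr::read_csv(pkg_extdata("cysteine_pa_gb.csv"),
                        comment = "#", show_col_types = FALSE)
  energy_ledger(df, values = "absolute")
}

#' @rdname cysteine_benchmark_table
#' @export
cysteine_seed_geometry <- function() {
  read_xyz(pkg_extdata("cysteine_seed_synthetic.xyz"))
}

#' @rdname cysteine_benchmark_table
#' @export
cysteine_torsions <- function() {
  read_torsions(pkg_extdata("cysteine_torsions_synthetic.yaml"))
}

pkg_extdata <- function(fname) {
  path <- system.file("extdata", fname, package = "protaff")
  if (!nzchar(path)) stop("packaged file not found: ", fname)
  path
}

#' Run the full toy-backend workflow
#'
#' Exercises every stage end to end on synthetic inputs: grid
#' enumeration over the configured torsions, optimisation of every
#' start through the toy potential, conformer assignment, synthetic
#' ledger generation for the neutral and protonated species, composite
#' assembly, and Boltzmann-mixture PA/GB evaluation against the
#' configured anchor. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config a [run_config()] list.
#' @return the run manifest: list with `config`, `stages` (tibble of
#'   stage names, status and output sizes), `search`, `pa_gb`, and the
#'   paths of the CSVs written to `config$out_dir` (if set).
#' @export
run_pipeline <- function(config = run_config()) {
  stage_rows <- list()
  note <- function(stage, n) {
    stage_rows[[length(stage_rows) + 1L]] <<-
      tibble::tibble(stage = stage, status = "complete", n_out = n)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(config$seed)
  pes <- run_stage("setup", do.call(toy_pes, config$pes_args))
  torsions <- purrr::map(seq_len(pes$n_torsions), function(i) {
    torsion_spec(axis = c(2L, 3L),
                 dihedral_atoms = c(1L, 2L, 3L, 4L),
                 moving_set = 4L,
                 step_deg = config$grid_step_deg,
                 name = paste0("phi", i))
  })
  grid <- run_stage("enumerate", enumerate_grid(torsions))
  note("enumerate", grid$n_points)

  backend <- toy_backend(pes)
  search <- run_stage("search", run_search(grid, backend,
                                           e_tol = config$e_tol))
  note("search", nrow(search$records))

  confs <- search$conformers |>
    dplyr::mutate(
      A = 1 + .data$relative_energy * 1e-2, # surrogate fingerprint
      n_imaginary = purrr::map_int(.data$angles, function(a) {
        sum(backend$frequencies(a) < 0)
      })
    )
  minima <- run_stage("dedup", {
    deduplicate(dplyr::rename(confs, energy = "energy"),
                e_tol = config$e_tol, a_tol = config$a_tol) |>
      filter_minima()
  })
  note("dedup", nrow(minima))

  n_conf <- max(nrow(minima), 2L)
  led_n <- run_stage("synth", generate_ledger(n_conf, site = "neutral",
                                              seed = config$seed))
  led_p <- generate_ledger(n_conf, site = "N", seed = config$seed + 1L)
  note("synth", 2L)

  thermal <- function(led, seed_off) {
    # synthetic thermal columns: small conformer-dependent corrections
    set.seed(config$seed + seed_off)
    asm <- assemble_benchmark(led)
    asm |>
      dplyr::mutate(
        d_h0 = .data$h_0,
        d_h298 = .data$h_0 + c(0, stats::rnorm(dplyr::n() - 1, 0, 0.15)),
        d_g298 = .data$h_0 + c(0, stats::rnorm(dplyr::n() - 1, 0, 0.4))
      )
  }
  asm_n <- run_stage("assemble", thermal(led_n, 100L))
  asm_p <- thermal(led_p, 200L)
  note("assemble", nrow(asm_n) + nrow(asm_p))

  pagb <- run_stage("pa-gb", site_pa_gb(asm_n, asm_p,
                                        anchor = config$anchor,
                                        temperature = config$temperature,
                                        site = "N"))
  note("pa-gb", nrow(pagb))

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      conformers = write_report(
        dplyr::select(minima, -dplyr::any_of(c("angles"))),
        file.path(config$out_dir, "conformers.csv")),
      neutral = write_report(asm_n, file.path(config$out_dir, "neutral.csv")),
      protonated = write_report(asm_p,
                                file.path(config$out_dir, "protonated.csv")),
      pa_gb = write_report(tibble::as_tibble(pagb),
                           file.path(config$out_dir, "pa_gb.csv"))
    )
  }

  list(
    config = config,
    stages = dplyr::bind_rows(stage_rows),
    search = search,
    pa_gb = pagb,
    paths = paths
  )
}

#' Pipeline configuration
#'
#' Collects the run parameters in one serialisable list: temperature
#' (298.15 K), standard pressure (1 bar), the deduplication tolerances
#' (0.01 kcal/mol, 3e-4 cm^-1), the 60-degree grid step, the toy
#' potential definition, the PA/GB anchor, the random seed and an
#' optional output directory.
#'
#' @param temperature K.
#' @param pressure Pa.
#' @param e_tol,a_tol deduplication tolerances (kcal/mol, cm^-1).
#' @param grid_step_deg torsional grid step in degrees.
#' @param pes_args arguments for [toy_pes()].
#' @param anchor lowest-conformer PA/GB anchor (kcal/mol).
#' @param seed integer random seed.
#' @param out_dir optional output directory for the stage CSVs.
#' @return a named list.
#' @export
run_config <- function(temperature = 298.15,
                       pressure = pa_constants$p_standard,
                       e_tol = 0.01, a_tol = 3e-4,
                       grid_step_deg = 60,
                       pes_args = list(
                         # two torsions, 3 x 2 wells, stationary points
                         # shifted off the 60-degree grid
                         amplitudes = rbind(c(0.8, 0, 2.0),
                                            c(0.6, 1.2, 0)),
                         phases = rbind(c(20, 0, 0), c(-40, 0, 0)),
                         coupling = matrix(c(0, 0.25, 0.25, 0), 2)
                       ),
                       anchor = list(pa_0k = 214.49, pa_298k = 215.79,
                                     gb_298k = 208.44),
                       seed = 1L, out_dir = NULL) {
  stopifnot(temperature > 0, pressure > 0, e_tol > 0, a_tol > 0,
            grid_step_deg > 0)
  list(temperature = temperature, pressure = pressure,
       e_tol = e_tol, a_tol = a_tol, grid_step_deg = grid_step_deg,
       pes_args = pes_args, anchor = anchor,
       seed = as.integer(seed), out_dir = out_dir)
}
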