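test_that("correction helpers equal their direct-subtraction oracles", {
  set.seed(21)
  n <- 25
  led <- energy_ledger(tibble::tibble(
    name = as.character(seq_len(n)),
    e_qz_f12b = rnorm(n),
    e_ae_cvtz = rnorm(n), e_fc_cvtz = rnorm(n),
    e_dk = rnorm(n), e_nodk = rnorm(n),
    e_ccsd_t_631g = rnorm(n), e_ccsdt_631g = rnorm(n),
    e_ccsdt_q_631g = rnorm(n),
    e_cc_dz = rnorm(n), e_cc_dz_mp2geom = rnorm(n)
  ), values = "absolute")
  expect_equal(core_correction(led)$d_core, led$e_ae_cvtz - led$e_fc_cvtz)
  expect_equal(relativistic_correction(led)$d_rel, led$e_dk - led$e_nodk)
  tq <- post_T_corrections(led)
  expect_equal(tq$d_t, led$e_ccsdt_631g - led$e_ccsd_t_631g)
  expect_equal(tq$d_q, led$e_ccsdt_q_631g - led$e_ccsdt_631g)
  expect_equal(geometry_effect(led)$geometry_effect,
               led$e_cc_dz_mp2geom - led$e_cc_dz)
  # identical columns give exactly zero
  led0 <- energy_ledger(tibble::tibble(
    e_ae_cvtz = rnorm(n), e_fc_cvtz = 0), values = "absolute")
  led0$e_fc_cvtz <- led0$e_ae_cvtz
  expect_true(all(core_correction(led0)$d_core == 0))
  # missing columns name the failing operation
  expect_error(core_correction(energy_ledger(tibble::tibble(e_dk = 1),
                                             values = "absolute")),
               "e_ae_cvtz")
})

test_that("printed benchmark rows assemble to their published composites", {
  t2 <- cysteine_benchmark_table("neutral")
  asm <- assemble_benchmark(dplyr::select(t2, -"d_e_e", -"d_h0",
                                          -"d_h298", -"d_g298"))
  x <- asm[asm$name == "X", ]
  expect_close(x$e_e, 2.66, tol = 0.015)
  expect_close(x$h_0, 2.30, tol = 0.015)
  # per-column rounding can shift a sum by one unit in the last digit
  iii <- asm[asm$name == "III", ]
  expect_close(iii$e_e, 1.66, tol = 0.015)
  # every row agrees with the printed composite within rounding
  expect_lt(max(abs(asm$e_e - t2$d_e_e)), 0.015)
  expect_lt(max(abs(asm$h_0 - t2$d_h0)), 0.015)

  # proton-affinity assembly (absolute rows)
  t6 <- cysteine_pa_table()
  asm6 <- assemble_benchmark(t6[t6$pair == "I-I_N", ])
  expect_close(asm6$e_e, 222.98, tol = 0.015)
  expect_close(asm6$h_0, 214.49, tol = 0.015)
})

test_that("published correction regularities hold in the fixtures", {
  t2 <- cysteine_benchmark_table("neutral")
  # the scalar-relativistic correction is nonpositive and small for the
  # neutral conformers
  expect_true(all(t2$d_rel <= 0))
  expect_true(all(t2$d_rel >= -0.02))
  t3 <- cysteine_benchmark_table("N")
  expect_close(t3$d_core[t3$name == "X_N"], 0.07, tol = 1e-9)
  # geometry effect: +0.01 for III_N, and 0.55 kcal/mol on average over
  # the nine non-reference S-protonated conformers
  ge_n <- geometry_effect(t3)
  expect_close(ge_n$geometry_effect[ge_n$name == "III_N"], 0.01, tol = 1e-9)
  t5 <- cysteine_benchmark_table("S")
  ge_s <- geometry_effect(t5)$geometry_effect
  expect_close(mean(abs(ge_s[-1])), 0.55, tol = 0.01)
})

test_that("composite assembly is linear and re-zeroing preserves differences", {
  led <- generate_ledger(6, seed = 13L)
  asm <- assemble_benchmark(led)
  ecols <- protaff:::ledger_energy_columns(led)
  scaled <- led
  for (cc in ecols) scaled[[cc]] <- scaled[[cc]] * 2.5
  attr(scaled, "values") <- attr(led, "values")
  asm2 <- assemble_benchmark(scaled)
  expect_equal(asm2$e_e, asm$e_e * 2.5, tolerance = 1e-12)
  # shifting an absolute ledger leaves relative spacings intact
  abs_led <- energy_ledger(dplyr::mutate(
    tibble::as_tibble(led),
    dplyr::across(dplyr::all_of(ecols), ~ .x + 100)), values = "absolute")
  asm3 <- assemble_benchmark(abs_led)
  expect_equal(diff(asm3$e_e), diff(asm$e_e), tolerance = 1e-9)
})

test_that("composite results survive a CSV round trip bit-exactly", {
  asm <- assemble_benchmark(generate_ledger(5, seed = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(asm, path)
  back <- read_ledger(path, values = "relative")
  for (cc in c("d_t", "d_q", "d_core", "d_rel", "e_e", "h_0")) {
    expect_identical(back[[cc]], asm[[cc]])
  }
})
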