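RT_298 <- pa_constants$R_kcal * 298.15

test_that("Boltzmann populations reproduce their closed forms", {
  p <- boltzmann_populations(rep(1.7, 5))
  expect_equal(p$x, rep(0.2, 5))
  p2 <- boltzmann_populations(c(0, RT_298 * log(2)))
  expect_equal(p2$x, c(2, 1) / 3, tolerance = 1e-12)
  expect_error(boltzmann_populations(numeric(0)), "empty")
  expect_error(boltzmann_populations(c(0, NaN)), "non-finite")
})

test_that("populations normalise, order by stability, and are gauge invariant", {
  set.seed(31)
  for (i in 1:10) {
    dg <- c(0, stats::runif(sample(2:12, 1), 0, 8))
    T_ <- stats::runif(1, 100, 600)
    p <- boltzmann_populations(dg, T_)
    expect_lt(abs(sum(p$x) - 1), 1e-12)
    expect_true(all(p$x > 0))
    expect_equal(which.max(p$x), which.min(dg))
    shifted <- boltzmann_populations(dg + 3.21, T_)
    expect_equal(p$x, shifted$x, tolerance = 1e-12)
  }
})

test_that("populations from a printed free-energy column match a direct evaluation", {
  t4 <- cysteine_benchmark_table("O")
  p <- boltzmann_populations(t4$d_g298, 298.15, id = t4$name)
  w_oracle <- exp(-t4$d_g298 / RT_298)
  expect_equal(p$x, w_oracle / sum(w_oracle), tolerance = 1e-14)
  # the reference conformer dominates the O-protonated ensemble
  expect_gt(p$x[p$id == "I_O"], 0.75)
})

test_that("mixture enthalpy is the population-weighted mean", {
  p <- boltzmann_populations(c(0, 0, 0))
  expect_equal(mixture_enthalpy(p, c(1, 2, 6)), 3)
  p1 <- boltzmann_populations(0)
  expect_equal(mixture_enthalpy(p1, 4.2), 4.2)
  expect_error(mixture_enthalpy(p, c(1, 2)), "misaligned")
})

test_that("ensemble free energy includes the mixing term", {
  expect_equal(mixture_free_energy(0), 0)
  expect_equal(mixture_free_energy(c(0, 0)), -RT_298 * log(2),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    g <- c(0, stats::runif(6, 0, 5))
    T_ <- stats::runif(1, 150, 500)
    RT <- pa_constants$R_kcal * T_
    gm <- mixture_free_energy(g, T_)
    x <- boltzmann_populations(g, T_)$x
    # identity: -RT ln sum exp(-G/RT) = <G> + RT sum x ln x
    expect_lt(abs(gm - (sum(x * g) + RT * sum(x * log(x)))), 1e-10)
    # the mixing term is nonpositive
    expect_lte(gm, sum(x * g) + 1e-12)
  }
})

test_that("single-conformer mixtures reduce to the anchor", {
  one <- tibble::tibble(d_h0 = 0, d_h298 = 0, d_g298 = 0)
  anchor <- list(pa_0k = 214.49, pa_298k = 215.79, gb_298k = 208.44)
  res <- site_pa_gb(one, one, anchor, site = "N")
  mix <- res[res$flavor == "mixture", ]
  low <- res[res$flavor == "lowest-conformer", ]
  expect_equal(mix$pa_0k, low$pa_0k, tolerance = 1e-12)
  expect_equal(mix$pa_298k, low$pa_298k, tolerance = 1e-12)
  expect_equal(mix$gb_298k, low$gb_298k, tolerance = 1e-12)
})

test_that("degenerate conformer sets cancel between the two species", {
  # three conformers degenerate with the anchor on both sides: the
  # enthalpy averages are zero and the mixing terms cancel exactly
  deg <- tibble::tibble(d_h0 = c(0, 0, 0), d_h298 = 0, d_g298 = 0)
  anchor <- list(pa_0k = 100, pa_298k = 101, gb_298k = 95)
  res <- site_pa_gb(deg, deg, anchor)
  expect_equal(res$pa_0k[2], 100, tolerance = 1e-12)
  expect_equal(res$gb_298k[2], 95, tolerance = 1e-12)
})

test_that("site mixtures from the benchmark tables preserve the site ordering", {
  t2 <- cysteine_benchmark_table("neutral")
  pa6 <- cysteine_pa_table()
  anchor_of <- function(s) {
    r <- pa6[pa6$site == s & pa6$flavor == "lowest-conformer", ]
    list(pa_0k = r$d_h0, pa_298k = r$d_h298, gb_298k = r$d_g298)
  }
  res <- purrr::map(c("N", "O", "S"), function(s) {
    site_pa_gb(t2, cysteine_benchmark_table(s), anchor_of(s), site = s)
  })
  mix_pa <- vapply(res, function(r) r$pa_298k[r$flavor == "mixture"],
                   numeric(1))
  expect_true(mix_pa[1] > mix_pa[2] && mix_pa[2] > mix_pa[3])
  # mixture GB sits below mixture PA at 298.15 K for every site
  for (r in res) {
    mix <- r[r$flavor == "mixture", ]
    expect_lt(mix$gb_298k, mix$pa_298k)
    expect_gt(mix$pa_298k, mix$pa_0k)
  }
})

test_that("glance reports the entropy lowering of the mixture", {
  t2 <- cysteine_benchmark_table("neutral")
  t3 <- cysteine_benchmark_table("N")
  res <- site_pa_gb(t2, t3, list(pa_0k = 214.49, pa_298k = 215.79,
                                 gb_298k = 208.44), site = "N")
  g <- glance(res)
  expect_equal(g$entropy_lowering,
               res$pa_298k[2] - res$gb_298k[2], tolerance = 1e-12)
  expect_equal(nrow(tidy(res)), 2L)
})
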