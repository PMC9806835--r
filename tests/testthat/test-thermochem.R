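test_that("zero-point energy follows its closed form and refuses imaginary modes", {
  expect_identical(zero_point_energy(numeric(0)), 0)
  f1 <- c(500, 1200); f2 <- c(900, 3000, 3100)
  expect_equal(zero_point_energy(c(f1, f2)),
               zero_point_energy(f1) + zero_point_energy(f2))
  # single 1000 cm^-1 mode against an independent constants evaluation
  k_oracle <- 6.62607015e-34 * 2.99792458e10 * 6.02214076e23 / 4184
  expect_equal(zero_point_energy(1000), 500 * k_oracle, tolerance = 1e-12)
  expect_error(zero_point_energy(c(1000, -50)), "not a minimum")
})

random_state <- function(seed, temperature = 298.15) {
  set.seed(seed)
  freqs <- sort(stats::runif(12, 60, 3500))
  rot <- list(A = stats::runif(1, 0.1, 2), B = stats::runif(1, 0.05, 0.1),
              C = stats::runif(1, 0.01, 0.05))
  rrho_state(freqs, rot, mass_u = stats::runif(1, 20, 200),
             temperature = temperature)
}

test_that("G = H - T S holds exactly and entropies are nonnegative", {
  for (s in 1:8) {
    st <- random_state(s, temperature = stats::runif(1, 50, 800))
    expect_lt(abs(st$g_total - (st$h_total - st$temperature * st$s_total / 1e3)),
              1e-12)
    expect_true(all(c(st$s_trans, st$s_rot, st$s_vib) >= 0))
  }
})

test_that("thermal contributions vanish in the low-temperature limit", {
  rot <- list(A = 1, B = 0.5, C = 0.3)
  st <- rrho_state(c(800, 1500), rot, mass_u = 50, temperature = 1e-3)
  expect_lt(st$h_trans + st$h_rot + st$h_vib, 1e-5)
  expect_lt(st$s_vib, 1e-12)
  expect_equal(st$h_total, st$zpe, tolerance = 1e-5)
})

test_that("each mode reaches equipartition at high temperature", {
  k <- pa_constants
  nu <- 100
  # deep classical regime: kT = 200 h c nu, where u/(exp(u) - 1) is
  # within 1 percent of the equipartition limit
  T_ <- 200 * nu * k$kcal_per_cm1 / k$R_kcal
  st <- rrho_state(nu, list(A = 1, B = 0.5, C = 0.3), 50, temperature = T_)
  expect_close(st$h_vib / (k$R_kcal * T_), 1, tol = 0.01)
})

test_that("enthalpy increases with temperature", {
  rot <- list(A = 0.3, B = 0.1, C = 0.08)
  freqs <- c(80, 300, 900, 1600, 3000)
  temps <- c(100, 200, 298.15, 400, 600)
  h <- vapply(temps, function(T_) {
    rrho_state(freqs, rot, 120, temperature = T_)$h_total
  }, numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("vibrational entropy decreases in every wavenumber", {
  base <- c(100, 500, 1500)
  s0 <- rrho_state(base, list(A = 1, B = .5, C = .3), 50)$s_vib
  for (j in seq_along(base)) {
    up <- base; up[j] <- up[j] * 1.2
    expect_lt(rrho_state(up, list(A = 1, B = .5, C = .3), 50)$s_vib, s0)
  }
})

test_that("the free proton reproduces its closed-form thermodynamics", {
  pt <- proton_thermo(298.15)
  expect_close(round(pt$h, 2), 1.48, tol = 1e-9)
  # Sackur-Tetrode at 1 bar via an independent evaluation
  kB <- 1.380649e-23; h <- 6.62607015e-34; NA_ <- 6.02214076e23
  m <- 1.00727646627 * 1.66053906660e-27
  q <- (2 * pi * m * kB * 298.15 / h^2)^1.5 * kB * 298.15 / 1e5
  s_oracle <- NA_ * kB * (log(q) + 2.5) / 4.184
  expect_equal(pt$s, s_oracle, tolerance = 1e-12)
  expect_close(pt$s, 26.04, tol = 0.01)
  # enthalpy is linear in T
  expect_equal(proton_thermo(2 * 298.15)$h, 2 * pt$h, tolerance = 1e-12)
  expect_error(proton_thermo(-1), "positive")
})

test_that("PA/GB of a conformer pair obeys the entropy identity", {
  pt <- proton_thermo(298.15)
  for (s in 1:5) {
    neu <- random_state(s)
    pro <- random_state(s + 100)
    res <- pa_gb_pair(neu, pro, pt, e_neutral = -10, e_protonated = -230)
    gap_oracle <- 298.15 * (neu$s_total + pt$s - pro$s_total) / 1e3
    expect_lt(abs((res$pa - res$gb) - gap_oracle), 1e-10)
  }
  # identical states cancel: PA and GB reduce to the bare proton terms
  neu <- random_state(1)
  res0 <- pa_gb_pair(neu, neu, pt)
  expect_equal(res0$pa, pt$h, tolerance = 1e-12)
  expect_equal(res0$gb, pt$g, tolerance = 1e-12)
  # temperature mismatch is an error
  expect_error(pa_gb_pair(random_state(1, 300), random_state(2), pt),
               "temperature mismatch")
})

test_that("imaginary modes and nonpositive temperatures are rejected", {
  rot <- list(A = 1, B = .5, C = .3)
  expect_error(rrho_state(c(500, -100), rot, 50), "not a minimum")
  expect_error(rrho_state(500, rot, 50, temperature = 0), "positive")
})
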