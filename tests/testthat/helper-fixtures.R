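# Small geometries and a frozen toy surface shared across the suite.

# ethane-like frame: two sp3 centres with three hydrogens each
ethane_like <- function() {
  r <- 1.54 / 2
  s <- sin(70.5 * pi / 180) * 1.09
  c_ <- cos(70.5 * pi / 180) * 1.09
  base <- function(x0, sgn, phase) {
    t(vapply(0:2, function(k) {
      a <- phase + k * 2 * pi / 3
      c(x0 + sgn * c_, s * cos(a), s * sin(a))
    }, numeric(3)))
  }
  mol_geom(
    c("C", "C", rep("H", 6)),
    rbind(c(-r, 0, 0), c(r, 0, 0),
          base(-r, -1, 0), base(r, 1, pi / 3)),
    label = "ethane-like toy"
  )
}

ethane_torsion <- function(step = 60) {
  torsion_spec(axis = c(1L, 2L), dihedral_atoms = c(3L, 1L, 2L, 6L),
               moving_set = 6:8, step_deg = step)
}

# independent dihedral evaluation: pure projection/atan2 route written
# against the same IUPAC convention, sharing no code with the package
oracle_dihedral <- function(p, atoms) {
  a <- p[atoms[1], ]; b <- p[atoms[2], ]
  c_ <- p[atoms[3], ]; d <- p[atoms[4], ]
  u <- c_ - b
  u <- u / sqrt(sum(u^2))
  v1 <- (a - b) - sum((a - b) * u) * u
  v2 <- (d - c_) - sum((d - c_) * u) * u
  x <- sum(v1 * v2)
  y <- sum(u * c(v1[2] * v2[3] - v1[3] * v2[2],
                 v1[3] * v2[1] - v1[1] * v2[3],
                 v1[1] * v2[2] - v1[2] * v2[1]))
  atan2(y, x) * 180 / pi
}

geom_xyz <- function(g) cbind(g$x, g$y, g$z)

# frozen two-torsion multi-well surface: 3 wells along phi1 (k = 3 term)
# times 2 along phi2 (k = 2 term), phases shifted off the 60-degree grid
test_pes <- function() {
  toy_pes(
    amplitudes = matrix(c(0.8, 0, 2.0,
                          0.6, 1.2, 0), 2, 3, byrow = TRUE),
    phases = matrix(c(20, 0, 0,
                      -40, 0, 0), 2, 3, byrow = TRUE),
    coupling = matrix(c(0, 0.25, 0.25, 0), 2)
  )
}

simple_torsions <- function(n, step = 60, period = 360, mirror_at = 0L) {
  lapply(seq_len(n), function(i) {
    torsion_spec(c(2L, 3L), c(1L, 2L, 3L, 4L), 4L, step_deg = step,
                 symmetry_period_deg = period,
                 mirror_equivalent = (i == mirror_at),
                 name = paste0("phi", i))
  })
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6f vs %.6f (tol %g)", object, expected, tol))
}
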