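#' Physical constants used throughout the package
#'
#' A single shared constant set (CODATA 2018) so that every module — the
#' rotational-constant code, the harmonic-oscillator thermochemistry, the
#' Boltzmann averaging — agrees to the last digit. All energies are
#' kcal/mol, temperatures K, pressures Pa, wavenumbers cm^-1 and
#' coordinates Angstrom unless a function says otherwise.
#'
#' @format A named list:
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{c_cm}{speed of light, cm/s}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{NA_}{Avogadro constant, 1/mol}
#'   \item{amu}{atomic mass unit, kg}
#'   \item{R_kcal}{molar gas constant, kcal mol^-1 K^-1}
#'   \item{kcal_per_cm1}{energy of one cm^-1 per mole, kcal/mol}
#'   \item{kcal_per_hartree}{hartree to kcal/mol}
#'   \item{p_standard}{standard pressure, Pa (1 bar)}
#'   \item{m_proton_u}{proton mass, u}
#' }
#' @export
pa_constants <- local({
  h <- 6.62607015e-34
  c_cm <- 2.99792458e10
  kB <- 1.380649e-23
  NA_ <- 6.02214076e23
  list(
    h = h,
    c_cm = c_cm,
    kB = kB,
    NA_ = NA_,
    amu = 1.66053906660e-27,
    R_kcal = 1.98720425864e-3,
    # h * c * N_A / 4184 = 2.859144e-3 kcal/mol per cm^-1
    kcal_per_cm1 = h * c_cm * NA_ / 4184,
    kcal_per_hartree = 627.509474,
    p_standard = 1e5,
    m_proton_u = 1.00727646627
  )
})

# IUPAC 2021 standard atomic weights (u) for the elements this package
# routinely meets; extend here if new elements are needed.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, Se = 78.971,
  B = 10.81, Si = 28.085
)

# Covalent radii in Angstrom (Cordero et al. consensus values), used by
# the distance-based bond perception.
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
  P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, Se = 1.20,
  B = 0.84, Si = 1.11
)

#' Standard atomic mass of an element symbol
#'
#' @param element character vector of element symbols (e.g. `"C"`).
#' @return numeric vector of masses in u.
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}
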