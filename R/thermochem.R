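#' Zero-point vibrational energy
#'
#' Half the sum of the harmonic wavenumbers, converted to kcal/mol with
#' the shared constant set. Imaginary modes (encoded as negative
#' wavenumbers) mean the structure is not a minimum and are an error.
#'
#' @param wavenumbers numeric vector of harmonic wavenumbers in cm^-1.
#' @return ZPE in kcal/mol.
#' @export
zero_point_energy <- function(wavenumbers) {
  if (length(wavenumbers) == 0L) return(0)
  if (any(wavenumbers <= 0)) {
    stop("not a minimum: imaginary or zero wavenumbers present")
  }
  sum(wavenumbers) / 2 * pa_constants$kcal_per_cm1
}

#' Rigid-rotor / harmonic-oscillator thermodynamic state
#'
#' Standard ideal-gas statistical mechanics for one conformer:
#' translation contributes `5/2 RT` to the enthalpy with Sackur-Tetrode
#' entropy; rotation contributes `3/2 RT` with the classical
#' asymmetric-top entropy (symmetry number 1 — the species handled here
#' are C1); each harmonic mode contributes its thermal population to
#' the vibrational enthalpy and entropy, with the zero-point energy
#' reported separately so that the total enthalpy at 0 K reduces to
#' the ZPE. Electronic degeneracy is 1 (closed shell). `G = H - T S`
#' holds exactly for the emitted state.
#'
#' @param wavenumbers harmonic wavenumbers in cm^-1 (all positive).
#' @param rot a [rotational_constants()] row (or any list with `A`,
#'   `B`, `C` in cm^-1).
#' @param mass_u molecular mass in u.
#' @param temperature K, > 0.
#' @param pressure Pa; default 1 bar.
#' @return a one-row `thermo_state` tibble: `temperature`, enthalpy
#'   pieces `h_trans`, `h_rot`, `h_vib`, `zpe`, `h_total` (kcal/mol),
#'   entropies `s_trans`, `s_rot`, `s_vib`, `s_total`
#'   (cal mol^-1 K^-1) and `g_total` (kcal/mol).
#' @export
rrho_state <- function(wavenumbers, rot, mass_u,
                       temperature = 298.15,
                       pressure = pa_constants$p_standard) {
  if (temperature <= 0) stop("temperature must be positive")
  if (any(wavenumbers <= 0)) {
    stop("not a minimum: imaginary or zero wavenumbers present")
  }
  k <- pa_constants
  R <- k$R_kcal
  T_ <- temperature

  h_trans <- 2.5 * R * T_
  s_trans <- sackur_tetrode(mass_u, T_, pressure)

  h_rot <- 1.5 * R * T_
  theta <- c(rot$A, rot$B, rot$C) * k$kcal_per_cm1 / R # rotational temps, K
  s_rot <- 1e3 * R * (log(sqrt(pi) / 1 *
                            sqrt(T_^3 / prod(theta))) + 1.5)

  zpe <- zero_point_energy(wavenumbers)
  th_v <- wavenumbers * k$kcal_per_cm1 / R # vibrational temps, K
  u <- th_v / T_
  h_vib <- R * sum(th_v / (exp(u) - 1))
  s_vib <- 1e3 * R * sum(u / (exp(u) - 1) - log(1 - exp(-u)))

  h_total <- h_trans + h_rot + h_vib + zpe
  s_total <- s_trans + s_rot + s_vib
  out <- tibble::tibble(
    temperature = T_,
    h_trans = h_trans, h_rot = h_rot, h_vib = h_vib, zpe = zpe,
    h_total = h_total,
    s_trans = s_trans, s_rot = s_rot, s_vib = s_vib, s_total = s_total,
    g_total = h_total - T_ * s_total / 1e3
  )
  class(out) <- c("thermo_state", class(out))
  out
}

# Sackur-Tetrode translational entropy in cal mol^-1 K^-1
sackur_tetrode <- function(mass_u, temperature, pressure) {
  k <- pa_constants
  m <- mass_u * k$amu
  q <- (2 * pi * m * k$kB * temperature / k$h^2)^1.5 *
    k$kB * temperature / pressure
  k$NA_ * k$kB * (log(q) + 2.5) / 4.184
}

#' Thermodynamics of the free proton
#'
#' An ideal-gas structureless particle: enthalpy `5/2 RT` (1.48
#' kcal/mol at 298.15 K), Sackur-Tetrode entropy at the standard
#' pressure (26.04 cal mol^-1 K^-1 at 298.15 K and 1 bar), and
#' `G = H - T S`.
#'
#' @param temperature K.
#' @param pressure Pa; default 1 bar.
#' @return a one-row tibble with `temperature`, `h`, `s`, `g`.
#' @export
proton_thermo <- function(temperature = 298.15,
                          pressure = pa_constants$p_standard) {
  if (temperature <= 0) stop("temperature must be positive")
  k <- pa_constants
  h <- 2.5 * k$R_kcal * temperature
  s <- sackur_tetrode(k$m_proton_u, temperature, pressure)
  tibble::tibble(temperature = temperature, h = h, s = s,
                 g = h - temperature * s / 1e3)
}

#' Proton affinity and gas-phase basicity of one conformer pair
#'
#' For the gaseous deprotonation `BH+ -> B + H+`, the proton affinity
#' is the enthalpy change and the gas-phase basicity the Gibbs
#' free-energy change:
#' `PA = H(B) + H(H+) - H(BH+)`, `GB = G(B) + G(H+) - G(BH+)`, so that
#' `PA - GB = T (S(B) + S(H+) - S(BH+)) / 1000` exactly.
#'
#' @param neutral,protonated `thermo_state` rows at the same
#'   temperature. Supply each species' electronic energy through
#'   `e_neutral` / `e_protonated` (kcal/mol, shared origin) — the RRHO
#'   state itself is electronic-energy-free.
#' @param proton a [proton_thermo()] row at the same temperature.
#' @param e_neutral,e_protonated electronic energies in kcal/mol.
#' @return a one-row tibble with `temperature`, `pa`, `gb`.
#' @export
pa_gb_pair <- function(neutral, protonated, proton,
                       e_neutral = 0, e_protonated = 0) {
  temps <- c(neutral$temperature, protonated$temperature,
             proton$temperature)
  if (max(temps) - min(temps) > 1e-9) {
    stop("temperature mismatch between states")
  }
  pa <- (e_neutral + neutral$h_total) + proton$h -
    (e_protonated + protonated$h_total)
  gb <- (e_neutral + neutral$g_total) + proton$g -
    (e_protonated + protonated$g_total)
  tibble::tibble(temperature = neutral$temperature, pa = pa, gb = gb)
}
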