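## Physical constants (CODATA 2018). Internal unit conventions:
## fields in mT, electron-spin frequencies in GHz, nuclear frequencies and
## hyperfine/quadrupole couplings in MHz, distances in Angstrom.

.PLANCK_J_S <- 6.62607015e-34     # exact
.BOHR_MAGNETON_J_T <- 9.2740100783e-24
.NUCLEAR_MAGNETON_J_T <- 5.0507837461e-27
.BOLTZMANN_J_K <- 1.380649e-23    # exact
.MU0_OVER_4PI <- 1e-7             # T m / A (SI, exact to current precision)
.G_ELECTRON <- 2.0023             # isotropic electronic g used throughout

## Bohr magneton over Planck constant: GHz per mT for unit g
.BETA_OVER_H_GHZ_PER_MT <- .BOHR_MAGNETON_J_T / .PLANCK_J_S * 1e-9 * 1e-3

#' Electron Zeeman conversion factor
#'
#' Frequency-per-field conversion \eqn{g\beta/h} for an electron with
#' isotropic g-value, in GHz per mT.
#'
#' @param g Electronic g-value (dimensionless).
#' @return Numeric scalar, GHz/mT.
#' @examples
#' electron_ghz_per_mt(2.0023)  # ~0.028 GHz/mT, i.e. ~28 GHz/T
#' @export
electron_ghz_per_mt <- function(g = .G_ELECTRON) {
  stopifnot(is.numeric(g), g > 0)
  g * .BETA_OVER_H_GHZ_PER_MT
}

## Registry of the nuclei handled by the package. nu_mhz_per_mt is the
## nuclear Zeeman frequency per applied field, g_n * mu_N / h.
.NUCLEUS_TABLE <- data.frame(
  isotope = c("1H", "2H", "14N"),
  spin    = c(0.5, 1, 1),
  g_n     = c(5.5856946893, 0.8574382338, 0.4037610),
  stringsAsFactors = FALSE
)
.NUCLEUS_TABLE$nu_mhz_per_mt <-
  .NUCLEUS_TABLE$g_n * .NUCLEAR_MAGNETON_J_T / .PLANCK_J_S * 1e-6 * 1e-3

#' Nucleus properties
#'
#' Looks up spin quantum number, nuclear g-factor and Larmor
#' frequency-per-field constant for a supported isotope.
#'
#' @param isotope One of `"1H"`, `"2H"`, `"14N"`.
#' @return List with elements `isotope`, `spin`, `g_n`, `nu_mhz_per_mt`.
#' @examples
#' nucleus_info("1H")$nu_mhz_per_mt * 1e3  # ~42.58 MHz/T
#' @export
nucleus_info <- function(isotope) {
  i <- match(isotope, .NUCLEUS_TABLE$isotope)
  if (is.na(i)) {
    stop("unknown isotope '", isotope, "'; supported: ",
         paste(.NUCLEUS_TABLE$isotope, collapse = ", "), call. = FALSE)
  }
  as.list(.NUCLEUS_TABLE[i, ])
}

#' Nuclear Larmor frequency at a field
#'
#' @param isotope Isotope label (see [nucleus_info()]).
#' @param field_mt Applied magnetic field, mT.
#' @return Larmor frequency in MHz.
#' @examples
#' nu_nmr("1H", 1845)   # ~79 MHz, the proton frequency near 1.85 T
#' @export
nu_nmr <- function(isotope, field_mt) {
  stopifnot(is.numeric(field_mt), all(field_mt > 0))
  nucleus_info(isotope)$nu_mhz_per_mt * field_mt
}

#' Point-dipole prefactor for a nucleus
#'
#' The constant \eqn{(\mu_0/4\pi)\, g_e \beta_e g_n \beta_n / h} expressed in
#' MHz A^3 (Angstrom cubed), so that the axial dipolar coupling of a point
#' dipole pair at distance r Angstrom is `prefactor / r^3` MHz. Computed from
#' physical constants at run time; for 1H it evaluates to about 79.06 MHz A^3
#' at g_e = 2.0023.
#'
#' @param isotope Isotope label.
#' @param g_e Electronic g-value.
#' @return Numeric scalar, MHz Angstrom^3.
#' @export
point_dipole_prefactor <- function(isotope, g_e = .G_ELECTRON) {
  nuc <- nucleus_info(isotope)
  pref_j_m3 <- .MU0_OVER_4PI * g_e * .BOHR_MAGNETON_J_T *
    nuc$g_n * .NUCLEAR_MAGNETON_J_T / .PLANCK_J_S
  # J m^3 / (J s) = Hz m^3; convert to MHz Angstrom^3: 1e-6 * 1e30
  pref_j_m3 * 1e24
}
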