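## Point-dipole model: treating the Mn(II) electron spin and a nucleus as
## point magnetic dipoles gives an axial dipolar tensor with principal
## values (-T, -T, +2T), unique axis along the inter-spin vector, and
##   T = (mu0/4pi) g_e beta_e g_n beta_n / (h r^3),
##   A_eff = A_iso + T (3 cos^2 theta_n - 1),
## where r is the metal-nucleus distance and theta_n the angle between the
## inter-spin vector and the applied field. The r^-3 law makes couplings a
## sub-0.1-Angstrom distance probe.

.check_r <- function(r_a) {
  if (any(r_a <= 1.5)) {
    stop("distance ", paste(signif(r_a[r_a <= 1.5], 3), collapse = ", "),
         " A is below the 1.5 A physical bound for H/N around Mn(II)",
         call. = FALSE)
  }
  invisible(r_a)
}

#' Axial dipolar coupling from distance
#'
#' @param r_a Metal-nucleus distance, Angstrom (> 1.5).
#' @param nucleus Isotope label.
#' @param g_e Electronic g-value used in the prefactor.
#' @return Axial dipolar parameter T, MHz (principal values -T, -T, +2T).
#' @examples
#' point_dipole_T(2.62)  # ~4.40 MHz for a water proton
#' @export
point_dipole_T <- function(r_a, nucleus = "1H", g_e = 2.0023) {
  stopifnot(is.numeric(r_a))
  .check_r(r_a)
  point_dipole_prefactor(nucleus, g_e) / r_a^3
}

#' Effective coupling from point-dipole geometry
#'
#' @param a_iso_mhz Isotropic coupling, MHz.
#' @param t_mhz Axial dipolar parameter T, MHz.
#' @param theta_deg Angle between the inter-spin vector and the field,
#'   degrees.
#' @return A_eff = A_iso + T (3 cos^2 theta - 1), MHz.
#' @examples
#' aeff_from_geometry(0, 4.1, 22)  # ~6.47 MHz, the H_w' coupling
#' @export
aeff_from_geometry <- function(a_iso_mhz, t_mhz, theta_deg) {
  stopifnot(all(theta_deg >= 0), all(theta_deg <= 180))
  a_iso_mhz + t_mhz * (3 * cos(theta_deg * pi / 180)^2 - 1)
}

#' Distance from an axial dipolar coupling
#'
#' Exact inverse of [point_dipole_T()].
#'
#' @param t_mhz Axial dipolar parameter, MHz (> 0).
#' @param nucleus Isotope label.
#' @param g_e Electronic g-value.
#' @return Distance in Angstrom.
#' @examples
#' distance_from_T(3.3)  # ~2.88 A
#' @export
distance_from_T <- function(t_mhz, nucleus = "1H", g_e = 2.0023) {
  if (any(t_mhz <= 0)) stop("T must be positive", call. = FALSE)
  (point_dipole_prefactor(nucleus, g_e) / t_mhz)^(1 / 3)
}

#' Distance sensitivity of the dipolar coupling
#'
#' First-order differential of the r^-3 law: dr = r dT / (3 T). A 100 kHz
#' coupling shift at the water-proton geometry (T ~ 3.3 MHz, r ~ 2.9 A)
#' corresponds to about 0.03 A. For a shift read from an ENDOR line position
#' rather than from the coupling itself, divide the line shift by |M_s| q
#' first (see `line_shift = TRUE`).
#'
#' @param r_a Distance, Angstrom.
#' @param t_mhz Dipolar coupling, MHz (> 0).
#' @param dt_mhz Coupling shift, MHz (or line-position shift when
#'   `line_shift = TRUE`).
#' @param line_shift If `TRUE`, interpret `dt_mhz` as a line-position shift
#'   at manifold `ms` and order `q` and convert it to a coupling shift.
#' @param ms,q Manifold and quantum order for the line-shift reading.
#' @return Distance change dr, Angstrom.
#' @examples
#' distance_sensitivity(2.91, 3.3, 0.100)  # ~0.029 A
#' @export
distance_sensitivity <- function(r_a, t_mhz, dt_mhz, line_shift = FALSE,
                                 ms = -5/2, q = 1) {
  if (any(t_mhz <= 0)) stop("T must be positive", call. = FALSE)
  if (line_shift) dt_mhz <- dt_mhz / abs(ms * q)
  r_a * dt_mhz / (3 * t_mhz)
}

#' Axial dipolar parameter to principal values and back
#'
#' @param t_mhz Axial parameter T.
#' @return `t_to_principal`: numeric length-3 (-T, -T, 2T).
#' @export
t_to_principal <- function(t_mhz) c(-t_mhz, -t_mhz, 2 * t_mhz)

#' @rdname t_to_principal
#' @param principal Length-3 principal values of an axial traceless tensor
#'   (two equal values; the unique one equals -2 times them).
#' @return `principal_to_t`: the axial parameter T (unique value / 2).
#' @export
principal_to_t <- function(principal) {
  stopifnot(length(principal) == 3L)
  if (abs(sum(principal)) > 1e-6) stop("tensor not traceless", call. = FALSE)
  s <- sort(principal)
  pairs <- c(abs(s[1] - s[2]), abs(s[2] - s[3]))
  uniq <- if (pairs[1] <= pairs[2]) s[3] else s[1]
  uniq / 2
}
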