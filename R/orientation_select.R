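## Orientation selection and tensor projection. At a chosen field position in
## the broad powder pattern only molecules with particular orientations are
## resonant; the hyperfine tensor projected onto that field direction yields
## the effective coupling A_eff that sets the first-order ENDOR/ELDOR-NMR
## line positions. Secular projection only: with nuclear Larmor frequencies
## up to ~185 MHz against couplings of a few MHz, pseudo-secular state
## mixing is negligible at these fields.

#' Euler angles (ZYZ intrinsic)
#'
#' The rotation convention used throughout: R = Rz(alpha) Ry(beta) Rz(gamma),
#' intrinsic, mapping tensor principal-axis coordinates into the molecular
#' frame. Example: `euler_angles(0, pi/2, 0)` carries the principal z-axis
#' onto the molecular x-axis.
#'
#' @param alpha,beta,gamma Angles in radians; alpha and gamma are wrapped to
#'   \[0, 2 pi), beta must lie in \[0, pi\].
#' @return Object of class `euler_angles`.
#' @export
euler_angles <- function(alpha = 0, beta = 0, gamma = 0) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma))
  if (beta < 0 || beta > pi) stop("beta must be in [0, pi]", call. = FALSE)
  structure(list(alpha = alpha %% (2 * pi), beta = beta,
                 gamma = gamma %% (2 * pi)),
            class = "euler_angles")
}

#' Rotation matrix from Euler angles
#'
#' @param eul [euler_angles()].
#' @return 3x3 orthogonal matrix R = Rz(alpha) Ry(beta) Rz(gamma); columns
#'   are the principal axes expressed in the molecular frame.
#' @export
euler_matrix <- function(eul) {
  stopifnot(inherits(eul, "euler_angles"))
  rz <- function(a) matrix(c(cos(a), sin(a), 0,
                             -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b),
                             0, 1, 0,
                             sin(b), 0, cos(b)), 3, 3)
  rz(eul$alpha) %*% ry(eul$beta) %*% rz(eul$gamma)
}

#' Hyperfine tensor of a coupled nucleus
#'
#' Isotropic part plus traceless dipolar principal values, with the
#' orientation of the principal axes in the molecular frame.
#'
#' @param nucleus Isotope label (`"1H"`, `"2H"`, `"14N"`; see
#'   [nucleus_info()]).
#' @param a_iso_mhz Isotropic coupling, MHz.
#' @param t_principal Length-3 numeric dipolar principal values
#'   (T_xx, T_yy, T_zz), MHz; must be traceless within 1e-6 MHz.
#' @param frame [euler_angles()] carrying principal axes into the molecular
#'   frame.
#' @param id Optional nucleus identity label (e.g. `"H_w"`, `"N_e_His26"`).
#' @param quad Optional [quadrupole_tensor()] (I >= 1 nuclei only).
#' @return Object of class `hyperfine_tensor`.
#' @export
hyperfine_tensor <- function(nucleus, a_iso_mhz, t_principal,
                             frame = euler_angles(), id = nucleus,
                             quad = NULL) {
  nuc <- nucleus_info(nucleus)
  stopifnot(is.numeric(a_iso_mhz), length(a_iso_mhz) == 1L,
            is.numeric(t_principal), length(t_principal) == 3L,
            inherits(frame, "euler_angles"))
  if (abs(sum(t_principal)) > 1e-6) {
    stop("dipolar principal values must be traceless (|trace| <= 1e-6 MHz); ",
         "got trace ", signif(sum(t_principal), 4), call. = FALSE)
  }
  if (!is.null(quad)) {
    stopifnot(inherits(quad, "quadrupole_tensor"))
    if (nuc$spin < 1) {
      stop("quadrupole tensor supplied for a spin-1/2 nucleus", call. = FALSE)
    }
  }
  structure(list(nucleus = nucleus, spin = nuc$spin,
                 nu_mhz_per_mt = nuc$nu_mhz_per_mt,
                 a_iso_mhz = unname(a_iso_mhz),
                 t_principal = unname(t_principal),
                 frame = frame, id = id, quad = quad),
            class = "hyperfine_tensor")
}

#' @export
print.hyperfine_tensor <- function(x, ...) {
  cat(sprintf("<hyperfine_tensor> %s (%s, I = %g): A_iso = %.3g MHz, T = (%.3g, %.3g, %.3g) MHz%s\n",
              x$id, x$nucleus, x$spin, x$a_iso_mhz, x$t_principal[1],
              x$t_principal[2], x$t_principal[3],
              if (!is.null(x$quad)) " + quadrupole" else ""))
  invisible(x)
}

#' Nuclear quadrupole tensor
#'
#' @param p_principal Length-3 traceless principal values (P_xx, P_yy,
#'   P_zz), MHz.
#' @param frame [euler_angles()] (principal axes to molecular frame).
#' @return Object of class `quadrupole_tensor`.
#' @export
quadrupole_tensor <- function(p_principal, frame = euler_angles()) {
  stopifnot(is.numeric(p_principal), length(p_principal) == 3L,
            inherits(frame, "euler_angles"))
  if (abs(sum(p_principal)) > 1e-6) {
    stop("quadrupole principal values must be traceless", call. = FALSE)
  }
  structure(list(p_principal = p_principal, frame = frame),
            class = "quadrupole_tensor")
}

## tensor in molecular-frame cartesian form
.tensor_molframe <- function(principal, frame) {
  r <- euler_matrix(frame)
  r %*% diag(principal) %*% t(r)
}

#' Molecular-frame dipolar tensor
#'
#' @param hft [hyperfine_tensor()].
#' @return 3x3 symmetric traceless matrix, MHz.
#' @export
dipolar_molframe <- function(hft) {
  stopifnot(inherits(hft, "hyperfine_tensor"))
  .tensor_molframe(hft$t_principal, hft$frame)
}

#' Effective hyperfine coupling along a field direction
#'
#' Secular projection A_eff = A_iso + n' T_mol n for unit field direction n
#' in the molecular frame, together with the ELDOR-NMR offset convention
#' offset = -M_s q A_eff (so the M_s = -5/2 manifold maps A_eff = 6.4 MHz
#' to +16 MHz on the positive branch).
#'
#' @param hft [hyperfine_tensor()].
#' @param direction Unit 3-vector (molecular frame).
#' @param ms Electronic manifold.
#' @param q Quantum order (>= 1).
#' @return Object of class `effective_coupling`: list with `a_eff_mhz`,
#'   `ms`, `q`, `offset_mhz`, `nucleus`, `id`.
#' @examples
#' h <- hyperfine_tensor("1H", 0, c(-4.1, -4.1, 8.2))
#' effective_coupling(h, c(0, 0, 1), -5/2, 1)  # A_eff = 8.2, offset = 20.5
#' @export
effective_coupling <- function(hft, direction, ms = -5/2, q = 1L) {
  stopifnot(inherits(hft, "hyperfine_tensor"),
            is.numeric(direction), length(direction) == 3L,
            q >= 1)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    stop("direction must be a unit vector (norm = ", signif(nrm, 4), ")",
         call. = FALSE)
  }
  tmol <- dipolar_molframe(hft)
  a_eff <- hft$a_iso_mhz + drop(direction %*% tmol %*% direction)
  structure(list(a_eff_mhz = a_eff, ms = ms, q = q,
                 offset_mhz = -ms * q * a_eff,
                 nucleus = hft$nucleus, id = hft$id),
            class = "effective_coupling")
}

#' Effective quadrupole coupling along a direction
#'
#' First-order quadrupole projection P_eff = n' P_mol n.
#'
#' @param quad [quadrupole_tensor()].
#' @param direction Unit 3-vector.
#' @return P_eff in MHz.
#' @export
effective_quadrupole <- function(quad, direction) {
  stopifnot(inherits(quad, "quadrupole_tensor"),
            is.numeric(direction), length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) stop("direction must be a unit vector",
                                call. = FALSE)
  pmol <- .tensor_molframe(quad$p_principal, quad$frame)
  drop(direction %*% pmol %*% direction)
}

#' Orientations resonant at a field position
#'
#' Returns all powder-grid orientations whose first-order resonance field
#' for the given transition lies within the excitation bandwidth of the
#' chosen field, with their solid-angle weights. At the extreme low-field
#' edge of a D < 0 pattern the set collapses to theta_zf = 0; at the extreme
#' high-field edge to (theta_zf = pi/2, phi_zf = pi/2).
#'
#' @param settings [spectrometer_settings()].
#' @param zfs [zfs_parameters()].
#' @param field_mt Chosen field position, mT.
#' @param bandwidth_mhz Excitation bandwidth (full width), MHz.
#' @param ms Lower manifold of the observed transition.
#' @param grid [make_powder_grid()] result.
#' @return data.frame with columns `theta`, `phi`, `weight` (weights
#'   renormalized to sum 1 within the set); attribute `"fraction"` holds
#'   the selected fraction of the total powder weight.
#' @export
resonant_orientations <- function(settings, zfs, field_mt,
                                  bandwidth_mhz = 100, ms = -5/2,
                                  grid = make_powder_grid()) {
  stopifnot(inherits(grid, "powder_grid"), bandwidth_mhz > 0)
  .check_ms(ms)
  geff <- electron_ghz_per_mt(settings$g)
  bracket <- .zfs_bracket(zfs, grid$theta, grid$phi)
  b <- (settings$nu_obs_ghz - (ms + 0.5) * bracket) / geff
  half_mt <- (bandwidth_mhz / 1000) / geff / 2
  sel <- abs(b - field_mt) <= half_mt
  if (!any(sel)) {
    stop("no orientations resonant at ", round(field_mt, 1),
         " mT for ms = ", ms, " within ", bandwidth_mhz, " MHz", call. = FALSE)
  }
  out <- data.frame(theta = grid$theta[sel], phi = grid$phi[sel],
                    weight = grid$weights[sel] / sum(grid$weights[sel]))
  attr(out, "fraction") <- sum(grid$weights[sel])
  out
}

#' Unit field direction from zero-field-frame angles
#'
#' @param theta_zf,phi_zf Angles of the field in the zero-field frame.
#' @return Unit 3-vector in the zero-field frame.
#' @export
direction_from_angles <- function(theta_zf, phi_zf = 0) {
  c(sin(theta_zf) * cos(phi_zf), sin(theta_zf) * sin(phi_zf), cos(theta_zf))
}
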