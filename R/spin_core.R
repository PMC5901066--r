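## First-order spin-Hamiltonian arithmetic for an S = 5/2 ion with zero-field
## splitting in a strong applied field. The working Hamiltonian is
##   H = g beta B S_z + D [S_z'^2 - S(S+1)/3] + E [S_x'^2 - S_y'^2]
## with the primed axes the zero-field principal frame. To first order, the
## M_s <-> M_s+1 transition is shifted from the Zeeman frequency by
##   (M_s + 1/2) [D (3 cos^2 th - 1) + 3 E sin^2 th cos 2 phi]
## where (th, phi) orient the field in the zero-field frame. In the equatorial
## plane (th = pi/2) the bracket spans -D +/- 3E as phi varies.

## valid lower manifolds of the five DeltaM_s = 1 transitions of S = 5/2
.MS_LOWER <- c(-5/2, -3/2, -1/2, 1/2, 3/2)
.MS_ALL <- seq(-5/2, 5/2, by = 1)

.check_ms <- function(ms) {
  if (!is.numeric(ms) || length(ms) != 1L ||
      !any(abs(ms - .MS_LOWER) < 1e-9)) {
    stop("ms must be one of {-5/2, -3/2, -1/2, +1/2, +3/2} ",
         "(the lower manifold of an M_s <-> M_s+1 transition)", call. = FALSE)
  }
  invisible(ms)
}

#' Spectrometer settings
#'
#' Observation frequency, electronic g-value and sample temperature for a
#' high-field EPR experiment.
#'
#' @param nu_obs_ghz Microwave observation frequency, GHz (94.0 for the
#'   W-band experiments this package targets).
#' @param g Isotropic electronic g-value; must lie in \[1.5, 2.5\].
#' @param temperature_k Sample temperature, K.
#' @return Object of class `spectrometer_settings`.
#' @examples
#' spectrometer_settings(94, 2.0023, 6)
#' @export
spectrometer_settings <- function(nu_obs_ghz = 94.0, g = 2.0023,
                                  temperature_k = 6.0) {
  stopifnot(is.numeric(nu_obs_ghz), length(nu_obs_ghz) == 1L, nu_obs_ghz > 0,
            is.numeric(g), length(g) == 1L,
            is.numeric(temperature_k), length(temperature_k) == 1L,
            temperature_k > 0)
  if (g < 1.5 || g > 2.5) stop("g must lie in [1.5, 2.5]", call. = FALSE)
  structure(list(nu_obs_ghz = nu_obs_ghz, g = g,
                 temperature_k = temperature_k),
            class = "spectrometer_settings")
}

#' @export
print.spectrometer_settings <- function(x, ...) {
  cat(sprintf("Spectrometer: nu_obs = %.4g GHz, g = %.5g, T = %.3g K\n",
              x$nu_obs_ghz, x$g, x$temperature_k))
  cat(sprintf("  center field nu_obs/(g beta) = %.1f mT\n", center_field(x)))
  invisible(x)
}

#' Zero-field-splitting parameters
#'
#' Axial (D) and rhombic (E) zero-field parameters of the S = 5/2 center.
#' The standard convention 0 <= E <= |D|/3 is enforced; out-of-convention
#' input is either rejected or re-canonicalized by principal-axis relabelling.
#'
#' @param d_ghz Signed axial parameter D, GHz. Must be nonzero.
#' @param e_ghz Rhombic parameter E, GHz.
#' @param canonicalize If `TRUE`, map an out-of-convention (D, E) pair to the
#'   equivalent canonical one (same principal values, axes relabelled); if
#'   `FALSE` (default), reject it.
#' @return Object of class `zfs_parameters` with fields `d_ghz`, `e_ghz`.
#' @examples
#' zfs_parameters(-10.60, 0.63)          # Mn-specific SOD site
#' zfs_parameters(3, 2, canonicalize = TRUE)
#' @export
zfs_parameters <- function(d_ghz, e_ghz = 0, canonicalize = FALSE) {
  stopifnot(is.numeric(d_ghz), length(d_ghz) == 1L,
            is.numeric(e_ghz), length(e_ghz) == 1L)
  if (d_ghz == 0) stop("D must be nonzero", call. = FALSE)
  if (e_ghz < 0 || e_ghz > abs(d_ghz) / 3 + 1e-12) {
    if (!canonicalize) {
      stop("(D, E) outside the convention 0 <= E <= |D|/3; ",
           "use canonicalize = TRUE to relabel axes", call. = FALSE)
    }
    de <- canonicalize_zfs(d_ghz, e_ghz)
    d_ghz <- de[1]; e_ghz <- de[2]
  }
  structure(list(d_ghz = d_ghz, e_ghz = e_ghz), class = "zfs_parameters")
}

#' @export
print.zfs_parameters <- function(x, ...) {
  cat(sprintf("ZFS: D = %.4g GHz, E = %.4g GHz (E/|D| = %.3f, |D|+E = %.4g GHz)\n",
              x$d_ghz, x$e_ghz, x$e_ghz / abs(x$d_ghz),
              abs(x$d_ghz) + x$e_ghz))
  invisible(x)
}

#' Canonicalize a (D, E) pair
#'
#' Any (D, E) defines zero-field principal values
#' (-D/3 + E, -D/3 - E, 2D/3). Relabelling which principal axis is called z
#' (and the x/y order) yields six equivalent (D, E) pairs; exactly one
#' satisfies the convention 0 <= E <= |D|/3 (up to ties at the boundary).
#'
#' @param d_ghz,e_ghz Arbitrary nonzero zero-field parameters, GHz.
#' @return Numeric length-2 vector `c(D, E)` in the canonical convention.
#' @export
canonicalize_zfs <- function(d_ghz, e_ghz) {
  pv <- c(-d_ghz / 3 + e_ghz, -d_ghz / 3 - e_ghz, 2 * d_ghz / 3)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2),
                c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  for (p in perms) {
    z <- pv[p[3]]; xy <- pv[p[1:2]]
    d <- 1.5 * z
    e <- (max(xy) - min(xy)) / 2
    if (d != 0 && e >= 0 && e <= abs(d) / 3 + 1e-12) {
      return(c(d, e))
    }
  }
  stop("could not canonicalize (D, E) = (", d_ghz, ", ", e_ghz, ")",
       call. = FALSE)  # unreachable for nonzero tensors
}

#' Field orientation in the zero-field frame
#'
#' @param theta_zf Polar angle from the D_zz axis, radians in \[0, pi\].
#' @param phi_zf Azimuth from D_xx, radians in \[0, 2 pi).
#' @return Object of class `orientation`.
#' @export
orientation <- function(theta_zf, phi_zf = 0) {
  stopifnot(is.numeric(theta_zf), length(theta_zf) == 1L,
            is.numeric(phi_zf), length(phi_zf) == 1L)
  if (theta_zf < 0 || theta_zf > pi) stop("theta_zf must be in [0, pi]",
                                          call. = FALSE)
  phi_zf <- phi_zf %% (2 * pi)
  structure(list(theta_zf = theta_zf, phi_zf = phi_zf), class = "orientation")
}

## vectorized workhorse used by the powder simulators: theta, phi plain
## numeric vectors, returns the first-order bracket in GHz
.zfs_bracket <- function(zfs, theta, phi) {
  ct2 <- cos(theta)^2
  zfs$d_ghz * (3 * ct2 - 1) + 3 * zfs$e_ghz * (1 - ct2) * cos(2 * phi)
}

#' First-order transition-frequency shift
#'
#' Shift of the M_s <-> M_s+1 transition frequency away from the electronic
#' Zeeman frequency, to first order in the zero-field interaction:
#' \deqn{(M_s + 1/2)\,[D (3\cos^2\theta - 1) + 3 E \sin^2\theta \cos 2\phi]}
#'
#' @param zfs [zfs_parameters()].
#' @param orient [orientation()] of the field in the zero-field frame.
#' @param ms Lower manifold M_s of the transition, one of
#'   -5/2, -3/2, -1/2, +1/2, +3/2.
#' @return Frequency shift in GHz.
#' @examples
#' z <- zfs_parameters(-10.60, 0.63)
#' firstorder_shift(z, orientation(0), -5/2)   # +42.40 GHz
#' @export
firstorder_shift <- function(zfs, orient, ms) {
  stopifnot(inherits(zfs, "zfs_parameters"), inherits(orient, "orientation"))
  .check_ms(ms)
  (ms + 0.5) * .zfs_bracket(zfs, orient$theta_zf, orient$phi_zf)
}

#' Center field of the spectrum
#'
#' The isotropic resonance field \eqn{\nu_{obs} h / (g\beta)}, mT.
#'
#' @param settings [spectrometer_settings()].
#' @return Field in mT.
#' @export
center_field <- function(settings) {
  stopifnot(inherits(settings, "spectrometer_settings"))
  settings$nu_obs_ghz / electron_ghz_per_mt(settings$g)
}

#' First-order resonance field
#'
#' Field at which the M_s <-> M_s+1 transition resonates for a given
#' orientation: \eqn{B = (\nu_{obs} - \mathrm{shift}) / (g\beta/h)}.
#'
#' @inheritParams firstorder_shift
#' @param settings [spectrometer_settings()].
#' @return Resonance field, mT.
#' @export
resonance_field <- function(settings, zfs, orient, ms) {
  shift <- firstorder_shift(zfs, orient, ms)
  b <- (settings$nu_obs_ghz - shift) / electron_ghz_per_mt(settings$g)
  if (b <= 0) {
    stop("non-positive resonance field (", round(b, 1),
         " mT): unphysical parameter combination", call. = FALSE)
  }
  b
}

## the canonical orientations used for turning-point labelling
.CANONICAL_ORIENTS <- list(
  zz = c(theta = 0, phi = 0),
  xx = c(theta = pi / 2, phi = 0),
  yy = c(theta = pi / 2, phi = pi / 2)
)

#' Canonical turning-point fields
#'
#' Resonance fields with the applied field along each zero-field principal
#' axis (zz: theta = 0; xx: theta = pi/2, phi = 0; yy: theta = pi/2,
#' phi = pi/2) for the requested manifolds. These are the labelled
#' turning-point positions of the powder pattern; the four used for the
#' (D, E) read-off are (zz, -5/2), (zz, -3/2), (xx, -5/2) and (yy, -5/2).
#'
#' @param settings [spectrometer_settings()].
#' @param zfs [zfs_parameters()].
#' @param manifolds Lower manifolds M_s to evaluate.
#' @return Object of class `turning_point_set`: a list with `positions`
#'   (data.frame of axis, ms, field_mt) and `center_mt`.
#' @examples
#' canonical_positions(spectrometer_settings(), zfs_parameters(-10.46, 0.33))
#' @export
canonical_positions <- function(settings, zfs, manifolds = c(-5/2, -3/2)) {
  rows <- do.call(rbind, lapply(manifolds, function(ms) {
    .check_ms(ms)
    do.call(rbind, lapply(names(.CANONICAL_ORIENTS), function(ax) {
      o <- .CANONICAL_ORIENTS[[ax]]
      data.frame(axis = ax, ms = ms,
                 field_mt = resonance_field(settings, zfs,
                                            orientation(o["theta"], o["phi"]),
                                            ms),
                 stringsAsFactors = FALSE)
    }))
  }))
  turning_point_set(rows, center_field(settings))
}

#' Turning-point set
#'
#' @param positions data.frame with columns `axis` ("xx"/"yy"/"zz"), `ms`
#'   (lower manifold), `field_mt`.
#' @param center_mt Center field nu_obs/(g beta), mT.
#' @return Object of class `turning_point_set`.
#' @export
turning_point_set <- function(positions, center_mt) {
  stopifnot(is.data.frame(positions),
            all(c("axis", "ms", "field_mt") %in% names(positions)),
            all(positions$axis %in% c("xx", "yy", "zz")),
            all(positions$field_mt > 0),
            is.numeric(center_mt), center_mt > 0)
  structure(list(positions = positions, center_mt = center_mt),
            class = "turning_point_set")
}

#' @export
print.turning_point_set <- function(x, ...) {
  cat(sprintf("Turning points (center %.1f mT):\n", x$center_mt))
  df <- x$positions
  df$offset_mt <- df$field_mt - x$center_mt
  print(df, row.names = FALSE)
  invisible(x)
}

.tp_lookup <- function(tp, axis, ms) {
  i <- which(tp$positions$axis == axis &
               abs(tp$positions$ms - ms) < 1e-9)
  if (length(i) == 0L) return(NA_real_)
  tp$positions$field_mt[i[1]]
}

#' Read off (D, E) from labelled turning points
#'
#' Inverts the first-order turning-point relations:
#' \deqn{D = (g\beta/h)\,\Delta B_{zz,-5/2}/4,\qquad
#'       E = (g\beta/h)\,[\Delta B_{xx,-5/2} - \Delta B_{yy,-5/2}]/12}
#' with field offsets measured from the center field, so a rigid field shift
#' leaves the result unchanged. Composition with [canonical_positions()] is
#' the identity on (D, E).
#'
#' @param tp [turning_point_set()] containing at least the (zz, -5/2),
#'   (zz, -3/2), (xx, -5/2) and (yy, -5/2) labels.
#' @param settings [spectrometer_settings()].
#' @return [zfs_parameters()]. If the recovered E/|D| exceeds 1/3 a warning
#'   is issued and the non-canonical values are returned with attribute
#'   `non_canonical = TRUE`.
#' @export
invert_turning_points <- function(tp, settings) {
  stopifnot(inherits(tp, "turning_point_set"),
            inherits(settings, "spectrometer_settings"))
  need <- list(c("zz", -5/2), c("zz", -3/2), c("xx", -5/2), c("yy", -5/2))
  b <- vapply(need, function(nm) .tp_lookup(tp, nm[1], as.numeric(nm[2])),
              numeric(1))
  if (anyNA(b)) {
    miss <- vapply(need[is.na(b)], function(nm)
      paste0("(", nm[1], ", ", nm[2], ")"), character(1))
    stop("turning-point set is missing the read-off labels: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  geff <- electron_ghz_per_mt(settings$g)
  db <- b - tp$center_mt
  d <- geff * db[1] / 4
  e <- geff * (db[3] - db[4]) / 12
  if (e < 0) {
    # xx/yy labels swapped relative to the sign convention: E is defined
    # non-negative, the swap is a pure relabelling
    e <- -e
  }
  if (e > abs(d) / 3 + 1e-9) {
    warning("recovered E/|D| = ", round(e / abs(d), 3),
            " exceeds 1/3; returning non-canonical values", call. = FALSE)
    out <- structure(list(d_ghz = d, e_ghz = e), class = "zfs_parameters")
    attr(out, "non_canonical") <- TRUE
    return(out)
  }
  zfs_parameters(d, e)
}

#' Boltzmann weight of an electronic manifold
#'
#' Relative population of manifold M_s under Zeeman-dominated energies
#' E(M_s) = M_s g beta B, normalized over the six manifolds of S = 5/2.
#' At 6 K and ~3.35 T the low-M_s manifolds dominate, which is why the
#' M_s = -5/2 and -3/2 transitions carry the outer turning points of the
#' low-temperature spectra.
#'
#' @param settings [spectrometer_settings()] (temperature is taken from it).
#' @param field_mt Applied field, mT.
#' @param ms Manifold, any of -5/2 ... +5/2 (vectorized).
#' @return Weight(s) in \[0, 1\], summing to 1 over the six manifolds.
#' @export
boltzmann_weight <- function(settings, field_mt, ms) {
  stopifnot(inherits(settings, "spectrometer_settings"),
            is.numeric(field_mt), all(field_mt > 0))
  if (!all(vapply(ms, function(m) any(abs(m - .MS_ALL) < 1e-9), logical(1)))) {
    stop("ms must be half-integers in -5/2 ... +5/2", call. = FALSE)
  }
  # E(ms)/k_B in K per mT of field
  e_over_k <- settings$g * .BOHR_MAGNETON_J_T * (field_mt * 1e-3) /
    .BOLTZMANN_J_K
  w_all <- exp(-outer(.MS_ALL, e_over_k) / settings$temperature_k)
  w_all <- sweep(w_all, 2, colSums(w_all), "/")
  idx <- vapply(ms, function(m) which.min(abs(m - .MS_ALL)), integer(1))
  res <- w_all[idx, , drop = FALSE]
  if (nrow(res) == 1L || ncol(res) == 1L) drop(res) else res
}
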