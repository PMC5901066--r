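## ENDOR and ELDOR-detected NMR line positions and spectra. All offsets are
## measured from q times the nuclear Larmor frequency; on the positive branch
## a single-quantum line of a nucleus with effective coupling A_eff in
## manifold M_s sits at -M_s q A_eff. Multiple-quantum transitions combine
## nuclear spin flips of one I >= 1 nucleus or of several nuclei coupled to
## the same electron; the single-nucleus I = 1 double-quantum line is purely
## hyperfine-determined (first-order quadrupole shifts of the two
## single-quantum steps cancel).

#' Gaussian spectral component
#'
#' One coupling contributing a Gaussian line per manifold, the unit spectra
#' are simulated from and fitted to. A matrix (distant-nucleus) line is an
#' ordinary component with `a_eff_mhz = 0`.
#'
#' @param a_eff_mhz Effective coupling, MHz (signed).
#' @param width_mhz Gaussian full width at half maximum, MHz.
#' @param amplitude Relative amplitude (>= 0).
#' @param nucleus Isotope label.
#' @param manifolds Manifolds M_s contributing.
#' @param id Optional label.
#' @return Object of class `spectral_component`.
#' @examples
#' spectral_component(6.4, 2.2)  # the larger water-proton component
#' @export
spectral_component <- function(a_eff_mhz, width_mhz = 2.2, amplitude = 1,
                               nucleus = "1H", manifolds = c(-5/2, -3/2),
                               id = NULL) {
  stopifnot(is.numeric(a_eff_mhz), length(a_eff_mhz) == 1L,
            is.numeric(width_mhz), width_mhz > 0, amplitude >= 0)
  nucleus_info(nucleus)  # validates
  structure(list(a_eff_mhz = a_eff_mhz, width_mhz = width_mhz,
                 amplitude = amplitude, nucleus = nucleus,
                 manifolds = manifolds,
                 id = if (is.null(id)) sprintf("%s@%.2fMHz", nucleus,
                                               a_eff_mhz) else id),
            class = "spectral_component")
}

#' @export
print.spectral_component <- function(x, ...) {
  cat(sprintf("<spectral_component> %s: A_eff = %.3g MHz, FWHM = %.3g MHz, amp = %.3g\n",
              x$id, x$a_eff_mhz, x$width_mhz, x$amplitude))
  invisible(x)
}

.line_list <- function(offset, intensity, tag) {
  if (any(intensity < 0)) stop("line intensities must be non-negative",
                               call. = FALSE)
  data.frame(offset_mhz = offset, intensity = intensity, tag = tag,
             stringsAsFactors = FALSE)
}

#' Single-quantum line positions
#'
#' For I = 1/2 the two branches sit at offsets -/+ M_s A_eff about zero
#' (positive branch at -M_s A_eff). For I = 1 a first-order quadrupole
#' interaction additionally splits each branch by +/- (3/2) P_eff.
#'
#' @param a_eff_mhz Effective coupling, MHz.
#' @param nucleus Isotope label.
#' @param ms Electronic manifold.
#' @param quad Optional [quadrupole_tensor()] (I >= 1 only); requires
#'   `direction`.
#' @param direction Unit field direction in the molecular frame (only used
#'   with `quad`).
#' @param p_eff_mhz Alternatively, a precomputed effective quadrupole
#'   projection, MHz.
#' @return Line list: data.frame with `offset_mhz`, `intensity`, `tag`.
#' @examples
#' sq_frequencies(6.4, "1H", -5/2)   # positive branch at +16 MHz
#' @export
sq_frequencies <- function(a_eff_mhz, nucleus = "1H", ms = -5/2,
                           quad = NULL, direction = NULL,
                           p_eff_mhz = NULL) {
  nuc <- nucleus_info(nucleus)
  if ((!is.null(quad) || !is.null(p_eff_mhz)) && nuc$spin < 1) {
    stop("quadrupole interaction supplied for a spin-1/2 nucleus",
         call. = FALSE)
  }
  base <- -ms * a_eff_mhz
  tag0 <- sprintf("%s SQ ms=%g", nucleus, ms)
  if (is.null(quad) && is.null(p_eff_mhz)) {
    if (a_eff_mhz == 0) {
      return(.line_list(0, 1, paste(tag0, "matrix")))
    }
    return(.line_list(c(base, -base), c(1, 1),
                      paste(tag0, c("branch+", "branch-"))))
  }
  if (is.null(p_eff_mhz)) {
    if (is.null(direction)) stop("direction required with a quadrupole tensor",
                                 call. = FALSE)
    p_eff_mhz <- effective_quadrupole(quad, direction)
  }
  shift <- 1.5 * p_eff_mhz
  .line_list(c(base + shift, base - shift, -base + shift, -base - shift),
             rep(0.5, 4),
             paste(tag0, c("branch+ q+", "branch+ q-",
                           "branch- q+", "branch- q-")))
}

#' Multiple-quantum line positions
#'
#' Combination lines of one or several nuclei coupled to the same electron
#' spin. The offset relative to the q-scaled Larmor reference is the sum of
#' -M_s Delta m_I A_eff over the participants. A single-nucleus I = 1
#' double-quantum transition carries no first-order quadrupole shift.
#'
#' @param participants data.frame (or list coercible to one) with columns
#'   `a_eff_mhz`, `nucleus`, `dm_i` (nuclear flip, |dm_i| <= 2 I).
#' @param ms Electronic manifold.
#' @return Line list with one row (the combination line) and tag recording
#'   the participants; attribute `"q"` gives the total quantum order.
#' @examples
#' # 14N DQ at the low-field edge: A_eff = 4 MHz, ms = -5/2 -> 20 MHz
#' mq_frequencies(data.frame(a_eff_mhz = 4, nucleus = "14N", dm_i = 2), -5/2)
#' @export
mq_frequencies <- function(participants, ms = -5/2) {
  p <- as.data.frame(participants, stringsAsFactors = FALSE)
  stopifnot(all(c("a_eff_mhz", "nucleus", "dm_i") %in% names(p)))
  q <- sum(abs(p$dm_i))
  if (q < 2) stop("multiple-quantum order q = sum |dm_i| must be >= 2",
                  call. = FALSE)
  for (i in seq_len(nrow(p))) {
    imax <- 2 * nucleus_info(p$nucleus[i])$spin
    if (abs(p$dm_i[i]) > imax + 1e-9) {
      stop("|dm_i| = ", abs(p$dm_i[i]), " exceeds 2I = ", imax, " for ",
           p$nucleus[i], call. = FALSE)
    }
  }
  offset <- sum(-ms * p$dm_i * p$a_eff_mhz)
  out <- .line_list(offset, 1,
                    paste0("q=", q, " [",
                           paste(sprintf("%s dm=%g A=%.3g", p$nucleus,
                                         p$dm_i, p$a_eff_mhz),
                                 collapse = "; "), "] ms=", ms))
  attr(out, "q") <- q
  out
}

#' Convert an offset to an effective coupling
#'
#' Inverse of the positive-branch convention: A_eff = -offset / (M_s q).
#'
#' @param offset_mhz Frequency offset from the q-scaled Larmor reference,
#'   MHz.
#' @param ms Electronic manifold (nonzero product ms * q required).
#' @param q Quantum order.
#' @return A_eff in MHz.
#' @examples
#' offset_to_aeff(-12.0, -5/2, 1)  # -4.8 MHz
#' offset_to_aeff(20, -5/2, 2)     #  4.0 MHz
#' @export
offset_to_aeff <- function(offset_mhz, ms, q = 1) {
  if (any(ms * q == 0)) stop("ms * q must be nonzero", call. = FALSE)
  -offset_mhz / (ms * q)
}

#' ELDOR-NMR forbiddenness weight
#'
#' A simple transition-probability model for multi-quantum line intensities:
#' proportional to (|anisotropic coupling| / nu_NMR)^(2q), normalized within
#' each quantum order. This is a documented heuristic standing in for the
#' full state-mixing calculation and is used only for relative intensities
#' within one q; it never moves line positions.
#'
#' @param aniso_mhz Anisotropic (dipolar) coupling magnitude, MHz.
#' @param nu_nmr_mhz Nuclear Larmor frequency, MHz.
#' @param q Quantum order.
#' @return Relative weights (normalized to max 1 within the input vector).
#' @export
eldor_forbiddenness <- function(aniso_mhz, nu_nmr_mhz, q = 1) {
  stopifnot(all(nu_nmr_mhz > 0), q >= 1)
  w <- (abs(aniso_mhz) / nu_nmr_mhz)^(2 * q)
  if (max(w) > 0) w / max(w) else w
}

#' Synthesize an ENDOR or ELDOR-NMR spectrum from Gaussian components
#'
#' Places Gaussian lines for every component and manifold. ENDOR spectra
#' include both branches; ELDOR kinds only the positive branch. For
#' `"eldor_dq"` the components are combined pairwise (two distinct
#' components, or a component with itself when only one is given); the
#' combination line has width sqrt(w_i^2 + w_j^2) and amplitude equal to the
#' product of the component amplitudes.
#'
#' @param components List of [spectral_component()].
#' @param axis_mhz Frequency-offset axis, MHz; should span all line
#'   positions by at least 3 widths (a warning reports clipped lines).
#' @param kind `"eldor_sq"`, `"eldor_dq"` or `"endor"`.
#' @param manifold_weights Optional numeric weights per manifold position
#'   (recycled across components); default equal weights.
#' @return [spectrum_1d()] of the requested kind.
#' @examples
#' ax <- seq(-5, 25, by = 0.05)
#' comps <- list(spectral_component(5.3, 2.2), spectral_component(6.4, 2.2))
#' sp <- synthesize_spectrum(comps, ax, "eldor_sq")
#' @export
synthesize_spectrum <- function(components, axis_mhz,
                                kind = c("eldor_sq", "eldor_dq", "endor"),
                                manifold_weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(components), length(components) >= 1L,
            all(vapply(components, inherits, logical(1),
                       "spectral_component")))
  lines <- .component_lines(components, kind, manifold_weights)
  amp <- numeric(length(axis_mhz))
  span <- range(axis_mhz)
  clipped <- FALSE
  for (i in seq_len(nrow(lines))) {
    sigma <- lines$width_mhz[i] / (2 * sqrt(2 * log(2)))
    if (lines$offset_mhz[i] < span[1] + 3 * sigma ||
        lines$offset_mhz[i] > span[2] - 3 * sigma) clipped <- TRUE
    amp <- amp + lines$intensity[i] *
      exp(-(axis_mhz - lines$offset_mhz[i])^2 / (2 * sigma^2))
  }
  if (clipped) {
    warning("some lines fall within 3 widths of the axis ends (clipped)",
            call. = FALSE)
  }
  spectrum_1d(axis_mhz, amp, kind = kind,
              meta = list(lines = lines,
                          axis_note = "offset from q*nu_NMR, MHz"))
}

## expand components into placed Gaussian lines for a given kind
.component_lines <- function(components, kind, manifold_weights = NULL) {
  if (kind == "eldor_dq") {
    idx <- if (length(components) == 1L) matrix(c(1L, 1L), 2)
           else utils::combn(length(components), 2L)
    rows <- lapply(seq_len(ncol(idx)), function(k) {
      ci <- components[[idx[1, k]]]; cj <- components[[idx[2, k]]]
      mss <- intersect(ci$manifolds, cj$manifolds)
      wts <- .manifold_wts(manifold_weights, length(mss))
      do.call(rbind, lapply(seq_along(mss), function(m) {
        data.frame(offset_mhz = -mss[m] * (ci$a_eff_mhz + cj$a_eff_mhz),
                   width_mhz = sqrt(ci$width_mhz^2 + cj$width_mhz^2),
                   intensity = ci$amplitude * cj$amplitude * wts[m],
                   tag = sprintf("DQ %s+%s ms=%g", ci$id, cj$id, mss[m]),
                   stringsAsFactors = FALSE)
      }))
    })
    return(do.call(rbind, rows))
  }
  rows <- lapply(components, function(cc) {
    wts <- .manifold_wts(manifold_weights, length(cc$manifolds))
    do.call(rbind, lapply(seq_along(cc$manifolds), function(m) {
      ms <- cc$manifolds[m]
      if (cc$a_eff_mhz == 0) {
        off <- 0
      } else {
        off <- -ms * cc$a_eff_mhz
        if (kind == "endor") off <- c(off, -off)
      }
      data.frame(offset_mhz = off, width_mhz = cc$width_mhz,
                 intensity = cc$amplitude * wts[m],
                 tag = sprintf("SQ %s ms=%g", cc$id, ms),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

.manifold_wts <- function(manifold_weights, n) {
  if (is.null(manifold_weights)) return(rep(1 / n, n))
  w <- rep_len(manifold_weights, n)
  w / sum(w)
}

#' Fit Gaussian components to a measured spectrum
#'
#' Nonlinear least squares of [synthesize_spectrum()] against a
#' background-subtracted spectrum, with a deterministic multi-start: A_eff
#' seeds are spaced 1 MHz across the coupling bounds, every admissible seed
#' combination is refined by Levenberg-Marquardt, the best residual wins and
#' ties go to the smaller couplings.
#'
#' @param spec [spectrum_1d()] (kinds `"eldor_sq"` or `"endor"`).
#' @param n_components Number of coupling components (>= 1).
#' @param manifolds Manifolds assumed to contribute.
#' @param aeff_bounds Length-2 coupling bounds, MHz.
#' @param width_bounds Length-2 FWHM bounds, MHz.
#' @param include_matrix If `TRUE`, add a fixed A_eff = 0 matrix component
#'   whose width and amplitude are fitted.
#' @return List of fitted [spectral_component()]s (sorted by A_eff), with
#'   attributes `"se"` (standard errors, when estimable), `"residual"`
#'   (root-mean-square misfit) and `"fit"` (the `nls.lm` object).
#' @export
fit_components <- function(spec, n_components = 2L,
                           manifolds = c(-5/2, -3/2),
                           aeff_bounds = c(1, 8), width_bounds = c(0.5, 6),
                           include_matrix = FALSE) {
  stopifnot(inherits(spec, "spectrum_1d"), n_components >= 1L,
            length(aeff_bounds) == 2L, diff(aeff_bounds) > 0)
  x <- spec$axis; yobs <- spec$amplitude
  kind <- if (spec$kind == "fieldsweep") "eldor_sq" else spec$kind
  nm <- if (include_matrix) 1L else 0L
  amp0 <- max(yobs)

  # pure-numeric forward model (equivalent to synthesize_spectrum on the
  # same components, but without any container construction: the residual
  # is evaluated thousands of times during the multi-start refinement)
  fwhm2sig <- 1 / (2 * sqrt(2 * log(2)))
  nman <- length(manifolds)
  both_branches <- kind == "endor"
  model <- function(par) {
    a <- par[seq_len(n_components)]
    w <- par[n_components + seq_len(n_components + nm)]
    am <- par[2 * n_components + nm + seq_len(n_components + nm)]
    amp <- numeric(length(x))
    for (i in seq_len(n_components)) {
      sig <- w[i] * fwhm2sig
      hgt <- am[i] / nman
      for (ms in manifolds) {
        amp <- amp + hgt * exp(-(x + ms * a[i])^2 / (2 * sig^2))
        if (both_branches) {
          amp <- amp + hgt * exp(-(x - ms * a[i])^2 / (2 * sig^2))
        }
      }
    }
    if (include_matrix) {
      sig <- w[n_components + 1L] * fwhm2sig
      amp <- amp + am[n_components + 1L] * exp(-x^2 / (2 * sig^2))
    }
    amp
  }
  resid_fn <- function(par) model(par) - yobs

  seeds <- seq(ceiling(aeff_bounds[1]), floor(aeff_bounds[2]), by = 1)
  if (length(seeds) < n_components) seeds <- seq(aeff_bounds[1],
                                                 aeff_bounds[2],
                                                 length.out = n_components)
  combos <- utils::combn(length(seeds) + n_components - 1L, n_components)
  # combinations with repetition via stars-and-bars index shift
  combos <- apply(combos, 2, function(k) seeds[k - seq_len(n_components) + 1L])
  combos <- matrix(combos, nrow = n_components)

  lower <- c(rep(aeff_bounds[1], n_components),
             rep(width_bounds[1], n_components + nm),
             rep(0, n_components + nm))
  upper <- c(rep(aeff_bounds[2], n_components),
             rep(width_bounds[2], n_components + nm),
             rep(Inf, n_components + nm))
  best <- NULL
  for (k in seq_len(ncol(combos))) {
    par0 <- c(sort(combos[, k]), rep(2, n_components + nm),
              rep(amp0, n_components + nm))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- fit$deviance
    if (is.null(best) || dev < best$deviance * (1 - 1e-9) ||
        (abs(dev - best$deviance) <= 1e-9 * max(dev, best$deviance) &&
         .lex_less(sort(fit$par[seq_len(n_components)]),
                   sort(best$par[seq_len(n_components)])))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("component fit failed to converge from any start", call. = FALSE)
  }
  par <- best$par
  ord <- order(par[seq_len(n_components)])
  a <- par[seq_len(n_components)][ord]
  w <- par[n_components + seq_len(n_components)][ord]
  am <- par[2 * n_components + nm + seq_len(n_components)][ord]
  out <- lapply(seq_len(n_components), function(i)
    spectral_component(a[i], w[i], am[i], manifolds = manifolds))
  if (include_matrix) {
    out <- c(out, list(spectral_component(
      0, par[2 * n_components + 1L], par[length(par)],
      manifolds = manifolds, id = "matrix")))
  }
  se <- tryCatch({
    s <- summary(best)
    s$coefficients[, "Std. Error"]
  }, error = function(e) rep(NA_real_, length(par)))
  attr(out, "se") <- se
  attr(out, "residual") <- sqrt(best$deviance / length(yobs))
  attr(out, "fit") <- best
  out
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Double-quantum spectral edges
#'
#' Extreme offsets of the pairwise two-proton combination lines of a
#' component set at a given manifold: the high edge is the sum of the two
#' largest positive-branch offsets, the low edge of the two smallest.
#'
#' @param components List of [spectral_component()] (a single component is
#'   paired with itself).
#' @param ms Electronic manifold.
#' @return Named numeric vector `c(low_mhz, high_mhz)`.
#' @examples
#' comps <- list(spectral_component(6.4, 2.2), spectral_component(5.3, 2.2))
#' dq_edges(comps, -5/2)  # high edge 29.25 MHz
#' @export
dq_edges <- function(components, ms = -5/2) {
  stopifnot(is.list(components), length(components) >= 1L)
  a <- vapply(components, `[[`, numeric(1), "a_eff_mhz")
  if (length(a) == 1L) a <- c(a, a)
  idx <- utils::combn(length(a), 2L)
  sums <- -ms * (a[idx[1, ]] + a[idx[2, ]])
  c(low_mhz = min(sums), high_mhz = max(sums))
}
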