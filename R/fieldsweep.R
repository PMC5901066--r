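## Powder (orientation-averaged) simulation of the field-swept echo spectrum
## and automated turning-point read-off. The simulator places a Gaussian
## absorption line at the first-order resonance field of every grid
## orientation and requested transition, weighted by solid angle and the
## Boltzmann population of the lower manifold; echo-detected spectra are
## absorption-shaped, not field-modulation derivatives.

#' Equal-area powder orientation grid
#'
#' @param n_theta,n_phi Number of polar / azimuthal samples (>= 2).
#' @param hemisphere_only If `TRUE` (default) sample theta in \[0, pi/2\],
#'   exploiting the inversion symmetry of the first-order pattern.
#' @return Object of class `powder_grid`: list with numeric vectors `theta`,
#'   `phi` and `weights` (solid-angle weights, summing to 1).
#' @examples
#' g <- make_powder_grid(10, 20)
#' sum(g$weights)  # 1
#' @export
make_powder_grid <- function(n_theta = 361, n_phi = 181,
                             hemisphere_only = TRUE) {
  stopifnot(n_theta >= 2, n_phi >= 2)
  theta_max <- if (hemisphere_only) pi / 2 else pi
  dth <- theta_max / n_theta
  th <- (seq_len(n_theta) - 0.5) * dth
  ph <- (seq_len(n_phi) - 0.5) * (2 * pi / n_phi)
  gr <- expand.grid(theta = th, phi = ph)
  w <- sin(gr$theta)
  w <- w / sum(w)
  structure(list(theta = gr$theta, phi = gr$phi, weights = w,
                 hemisphere_only = hemisphere_only),
            class = "powder_grid")
}

#' @export
print.powder_grid <- function(x, ...) {
  cat(sprintf("<powder_grid> %d orientations (%s)\n", length(x$theta),
              if (x$hemisphere_only) "hemisphere" else "full sphere"))
  invisible(x)
}

## deposit stick weights onto a regular axis with linear splitting between
## the two neighbouring bins, then convolve with a Gaussian of FWHM fwhm
.sticks_to_spectrum <- function(axis, positions, weights, fwhm) {
  n <- length(axis)
  step <- axis[2] - axis[1]
  amp <- numeric(n)
  pos_idx <- (positions - axis[1]) / step + 1
  inside <- pos_idx >= 1 & pos_idx <= n
  clipped <- sum(weights[!inside])
  if (any(inside)) {
    pi_in <- pos_idx[inside]; w_in <- weights[inside]
    lo <- floor(pi_in); frac <- pi_in - lo
    hi <- pmin(lo + 1, n)
    s1 <- rowsum(w_in * (1 - frac), lo)
    amp[as.integer(rownames(s1))] <- amp[as.integer(rownames(s1))] + s1[, 1]
    s2 <- rowsum(w_in * frac, hi)
    amp[as.integer(rownames(s2))] <- amp[as.integer(rownames(s2))] + s2[, 1]
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / step))
  kx <- (-half:half) * step
  kernel <- exp(-kx^2 / (2 * sigma^2))
  kernel <- kernel / sum(kernel)
  sm <- stats::convolve(c(numeric(half), amp, numeric(half)), rev(kernel),
                        type = "open")
  # "open" convolution of length (n + 2*half) + (2*half+1) - 1; center slice
  sm <- sm[(2 * half + 1):(2 * half + n)]
  list(amplitude = sm, clipped_fraction = clipped / sum(weights))
}

#' Simulate a powder field-swept echo spectrum
#'
#' Sums Gaussian absorption lines over a powder grid and the requested
#' electronic transitions. Line centers come from [resonance_field()];
#' amplitudes are solid-angle weight times the Boltzmann population of the
#' lower manifold at the sample temperature.
#'
#' @param settings [spectrometer_settings()].
#' @param zfs [zfs_parameters()].
#' @param grid [make_powder_grid()] result; default 361 x 181 hemisphere
#'   (converged to < 1% ripple at the default linewidth).
#' @param field_axis Field axis in mT; default spans all canonical turning
#'   points of the requested transitions plus 5 linewidths, step
#'   linewidth/5.
#' @param linewidth_mt Gaussian FWHM of the single-orientation line, mT.
#' @param transitions Lower manifolds M_s to include; default all five
#'   DeltaM_s = 1 transitions.
#' @return [spectrum_1d()] of kind `"fieldsweep"`. A warning reports the
#'   clipped stick-weight fraction if the axis is too narrow.
#' @examples
#' s <- spectrometer_settings(94, 2.0023, 6)
#' sp <- simulate_fieldsweep(s, zfs_parameters(-10.60, 0.63),
#'                           transitions = c(-5/2, -3/2))
#' @export
simulate_fieldsweep <- function(settings, zfs, grid = make_powder_grid(),
                                field_axis = NULL, linewidth_mt = 10,
                                transitions = c(-5/2, -3/2, -1/2, 1/2, 3/2)) {
  stopifnot(inherits(settings, "spectrometer_settings"),
            inherits(zfs, "zfs_parameters"), inherits(grid, "powder_grid"),
            linewidth_mt > 0)
  lapply(transitions, .check_ms)
  geff <- electron_ghz_per_mt(settings$g)
  b0 <- center_field(settings)
  if (is.null(field_axis)) {
    cp <- canonical_positions(settings, zfs, manifolds = transitions)
    rng <- range(c(cp$positions$field_mt, b0))
    field_axis <- seq(rng[1] - 5 * linewidth_mt, rng[2] + 5 * linewidth_mt,
                      by = linewidth_mt / 5)
  }
  bracket <- .zfs_bracket(zfs, grid$theta, grid$phi)
  positions <- numeric(0); weights <- numeric(0)
  for (ms in transitions) {
    b <- (settings$nu_obs_ghz - (ms + 0.5) * bracket) / geff
    w <- grid$weights * boltzmann_weight(settings, b0, ms)
    positions <- c(positions, b)
    weights <- c(weights, w)
  }
  res <- .sticks_to_spectrum(field_axis, positions, weights, linewidth_mt)
  if (res$clipped_fraction > 1e-6) {
    warning(sprintf("field axis too narrow: %.2f%% of intensity clipped",
                    100 * res$clipped_fraction), call. = FALSE)
  }
  spectrum_1d(field_axis, res$amplitude, kind = "fieldsweep",
              meta = list(settings = settings, zfs = zfs,
                          linewidth_mt = linewidth_mt,
                          transitions = transitions,
                          axis_note = "field in mT, absorption lineshape"))
}

## smoothed amplitude + derivative used by the feature finder
.smooth_spec <- function(y, window_pts) {
  n <- max(5L, window_pts)
  if (n %% 2L == 0L) n <- n + 1L
  if (n >= length(y)) return(y)
  signal::sgolayfilt(y, p = 2, n = n)
}

.local_maxima <- function(y) {
  which(diff(sign(diff(y))) == -2) + 1L
}

## local maxima of y with prominence (drop to the higher flanking minimum)
## of at least min_prom
.prominent_maxima <- function(y, min_prom) {
  lm <- .local_maxima(y)
  if (!length(lm)) return(integer(0))
  keep <- vapply(lm, function(i) {
    left <- if (i > 1L) min(y[max(1L, i - 200L):i]) else y[i]
    right <- if (i < length(y)) min(y[i:min(length(y), i + 200L)]) else y[i]
    (y[i] - max(left, right)) >= min_prom
  }, logical(1))
  lm[keep]
}

#' Locate labelled turning points in a field-swept spectrum
#'
#' Deterministic replacement for the visual read-off: the spectrum is
#' Savitzky-Golay smoothed; the outer edges are found as 5%-of-maximum
#' onsets refined to the extremum of the first derivative (a Gaussian-blurred
#' powder edge is an erf step whose steepest point sits at the true edge);
#' the interior (zz, -3/2) step is found as a derivative maximum near half
#' the (zz, -5/2) offset; the intermediate-axis singularity (yy, -5/2) is
#' the outermost local maximum between the center and the far edge. Label
#' assignment tries both signs of D (or uses `zfs_guess`) and keeps the
#' self-consistent one.
#'
#' @param spec [spectrum_1d()] of kind `"fieldsweep"` with resolved edges.
#' @param settings [spectrometer_settings()].
#' @param zfs_guess Optional [zfs_parameters()]; only its sign of D is used.
#' @param linewidth_mt Expected linewidth (mT); default from `spec$meta` or
#'   10.
#' @param threshold Edge-onset threshold as a fraction of the smoothed
#'   maximum (default 0.05).
#' @param window_pts Smoothing window in points (default 3 axis steps,
#'   minimum 5).
#' @return [turning_point_set()] with the four read-off labels.
#' @export
locate_turning_points <- function(spec, settings, zfs_guess = NULL,
                                  linewidth_mt = NULL, threshold = 0.05,
                                  window_pts = 3L) {
  stopifnot(inherits(spec, "spectrum_1d"), spec$kind == "fieldsweep")
  if (is.null(linewidth_mt)) {
    linewidth_mt <- if (!is.null(spec$meta$linewidth_mt))
      spec$meta$linewidth_mt else 10
  }
  x <- spec$axis
  step <- x[2] - x[1]
  y <- .smooth_spec(spec$amplitude, window_pts)
  y <- y - min(y)
  m <- max(y)
  if (m <= 0) stop("flat spectrum: no features found", call. = FALSE)
  dy <- c(0, diff(y)) / step
  # heavier smoothing (~2.5 linewidths) for peak picking and level walks;
  # noise local maxima are additionally rejected by a prominence filter
  # whose floor comes from the raw (pre-smoothing) noise level
  y2 <- .smooth_spec(spec$amplitude,
                     max(9L, round(2.5 * linewidth_mt / step)))
  y2 <- y2 - min(y2)
  b0 <- center_field(settings)
  above <- which(y >= threshold * m)
  if (length(above) < 3L) stop("no features above threshold", call. = FALSE)
  nf_raw <- stats::mad(diff(spec$amplitude)) / sqrt(2)
  noise_floor <- max(stats::mad(diff(y)) / sqrt(2), 0.3 * nf_raw)
  peaks <- .prominent_maxima(y2, max(0.02 * max(y2), nf_raw))

  # minimum step contrast for an edge to count as a read-off feature; the
  # outer zz plateau can be ~1-2% of a dominant central -1/2 line
  need <- max(4 * noise_floor, 0.005 * max(y2))
  # level just inside an edge minus level just outside it
  edge_contrast <- function(b_edge, low_side) {
    sgn <- if (low_side) 1 else -1   # inside lies up-field of a low edge
    inner <- y2[x >= b_edge + min(sgn * 0.5, sgn * 2.5) * linewidth_mt &
                  x <= b_edge + max(sgn * 0.5, sgn * 2.5) * linewidth_mt]
    outer <- y2[x >= b_edge - max(sgn * 1.5, sgn * 3.5) * linewidth_mt &
                  x <= b_edge - min(sgn * 1.5, sgn * 3.5) * linewidth_mt]
    if (!length(inner) || !length(outer)) return(Inf)
    stats::median(inner) - stats::median(outer)
  }

  # onset at the threshold, then staircase walk-out: a weak outer plateau
  # (e.g. the thin zz edge of a near-axial pattern next to its strong
  # perpendicular divergence) is recovered by repeatedly extending the
  # onset to the outermost point still above a fraction of the local level,
  # guarded by the noise floor; the edge proper is then the derivative
  # extremum nearby (a Gaussian-blurred step is steepest at the true edge).
  # An edge whose step contrast stays below the noise floor (e.g. the faint
  # outer turning point of a weakly populated M_s = +3/2 transition) is
  # rejected, and the search jumps inward to the next genuine step.
  find_edge <- function(low, lim) {
    keepable <- if (low) which(seq_along(x) >= lim)
                else which(seq_along(x) <= lim)
    onset_pool <- intersect(above, keepable)
    if (!length(onset_pool)) return(NA_integer_)
    on <- if (low) onset_pool[1] else onset_pool[length(onset_pool)]
    repeat {
      inside <- if (low) which(x >= x[on] & x <= x[on] + 2 * linewidth_mt)
                else which(x <= x[on] & x >= x[on] - 2 * linewidth_mt)
      lev <- stats::median(y[inside])
      # small enough to step down from a dominant central -1/2 line to the
      # thin zz plateau (~2% of the central intensity at 6 K)
      thr <- max(0.03 * lev, 4 * noise_floor)
      outw <- if (low) which(x < x[on] & y >= thr & seq_along(x) >= lim)
              else which(x > x[on] & y >= thr & seq_along(x) <= lim)
      if (!length(outw)) break
      cand <- if (low) min(outw) else max(outw)
      if (cand == on) break
      on <- cand
    }
    win <- which(abs(x - x[on]) <= 3 * linewidth_mt)
    if (low) win[which.max(dy[win])] else win[which.min(dy[win])]
  }
  find_real_edge <- function(low) {
    lim <- if (low) 1L else length(x)
    for (iter in 1:6) {
      e <- find_edge(low, lim)
      if (is.na(e)) return(NA_integer_)
      if (edge_contrast(x[e], low) >= need) return(e)
      # jump past the spurious outer plateau: to the outermost point whose
      # level clears the rejected edge's level by the required contrast
      lev_sp <- y2[e]
      cand <- if (low) which(y2 >= lev_sp + need & seq_along(x) > e)
              else which(y2 >= lev_sp + need & seq_along(x) < e)
      if (!length(cand)) return(NA_integer_)
      lim <- if (low) min(cand) else max(cand)
    }
    NA_integer_
  }
  i_lo <- find_real_edge(TRUE)
  i_hi <- find_real_edge(FALSE)
  if (is.na(i_lo) || is.na(i_hi)) {
    stop("fewer than four assignable turning-point features: no outer ",
         "edges with step contrast above the noise floor", call. = FALSE)
  }
  b_lo <- x[i_lo]; b_hi <- x[i_hi]
  # strongest off-center prominent peak over both sides, used to compare
  # the two sign hypotheses
  in_side <- (x[peaks] > b0 + 2 * linewidth_mt &
                x[peaks] <= b_hi + linewidth_mt) |
             (x[peaks] < b0 - 2 * linewidth_mt &
                x[peaks] >= b_lo - linewidth_mt)
  side_best <- if (any(in_side)) max(y2[peaks[in_side]]) else 0

  try_hypothesis <- function(d_negative) {
    # for D < 0 the (zz, -5/2) edge is on the low-field side
    b_zz <- if (d_negative) b_lo else b_hi
    b_xx <- if (d_negative) b_hi else b_lo
    db_zz <- b_zz - b0
    if (abs(db_zz) < 4 * linewidth_mt) return(NULL)
    # interior step of the -3/2 <-> -1/2 transition at half the zz offset
    target <- b0 + db_zz / 2
    win <- abs(x - target) <= pmax(5 * linewidth_mt, 0.15 * abs(db_zz))
    if (!any(win)) return(NULL)
    cand <- which(win)
    i32 <- if (d_negative) cand[which.max(dy[cand])]
           else cand[which.min(dy[cand])]
    b_zz32 <- x[i32]
    # yy singularity: the strongest prominent maximum between the center
    # and the xx edge (the intermediate-axis divergence dominates its side
    # of the pattern). If the pick is actually the -3/2 counterpart (which
    # sits at exactly half the -5/2 offset), a peak near twice its offset
    # exists and is taken instead.
    if (d_negative) {
      sel <- peaks[x[peaks] > b0 + 2 * linewidth_mt &
                     x[peaks] <= b_xx + linewidth_mt]
    } else {
      sel <- peaks[x[peaks] < b0 - 2 * linewidth_mt &
                     x[peaks] >= b_xx - linewidth_mt]
    }
    if (!length(sel)) return(NULL)
    i_yy <- sel[which.max(y2[sel])]
    dbl <- b0 + 2 * (x[i_yy] - b0)
    outer <- sel[abs(x[sel] - dbl) <= max(2 * linewidth_mt,
                                          0.05 * abs(dbl - b0))]
    if (length(outer)) i_yy <- outer[which.max(y2[outer])]
    b_yy <- x[i_yy]
    # score: half-offset self-consistency of the interior -3/2 step, plus a
    # comparison of the two sides' strongest peaks -- the side carrying the
    # intermediate-axis powder divergence is the xx/yy side, while the zz
    # side only has steps and smoothing artifacts at plateau level
    side_peak <- y2[i_yy]
    score <- abs((b_zz32 - b0) - db_zz / 2) / abs(db_zz) +
      0.5 * (1 - side_peak / max(side_best, side_peak))
    list(b_zz = b_zz, b_zz32 = b_zz32, b_xx = b_xx, b_yy = b_yy,
         score = score)
  }

  hyps <- list()
  both <- NULL
  if (!is.null(zfs_guess)) {
    hyps[[1]] <- try_hypothesis(zfs_guess$d_ghz < 0)
  } else {
    both <- list(neg = try_hypothesis(TRUE), pos = try_hypothesis(FALSE))
    hyps <- Filter(Negate(is.null), both)
    if (length(hyps) == 2L) {
      hyps <- hyps[order(vapply(hyps, `[[`, numeric(1), "score"))[1]]
    }
  }
  hyps <- Filter(Negate(is.null), hyps)
  if (length(hyps) == 0L || hyps[[1]]$score > 0.35) {
    found <- sprintf("edges at %.1f and %.1f mT", b_lo, b_hi)
    stop("fewer than four assignable turning-point features (", found, ")",
         call. = FALSE)
  }
  h <- hyps[[1]]
  out <- turning_point_set(
    data.frame(axis = c("zz", "zz", "xx", "yy"),
               ms = c(-5/2, -3/2, -5/2, -5/2),
               field_mt = c(h$b_zz, h$b_zz32, h$b_xx, h$b_yy),
               stringsAsFactors = FALSE),
    b0)
  if (!is.null(both)) {
    attr(out, "assignment_scores") <-
      vapply(both, function(hh) if (is.null(hh)) NA_real_ else hh$score,
             numeric(1))
  }
  out
}

#' Extract (D, E) from a field-swept spectrum
#'
#' Composition of [locate_turning_points()] and [invert_turning_points()].
#' Per-parameter uncertainties propagated from the linewidth are attached as
#' attribute `"uncertainty"` (sd_D = g beta/h * FWHM/4 / 4 per edge is the
#' read-off sensitivity; sd_E combines the two high-field labels).
#'
#' @inheritParams locate_turning_points
#' @param ... Passed on to [locate_turning_points()].
#' @return [zfs_parameters()] with attribute `uncertainty` (named vector
#'   `d_ghz`, `e_ghz`).
#' @export
extract_zfs <- function(spec, settings, ...) {
  tp <- locate_turning_points(spec, settings, ...)
  zfs <- invert_turning_points(tp, settings)
  lw <- if (!is.null(spec$meta$linewidth_mt)) spec$meta$linewidth_mt else 10
  geff <- electron_ghz_per_mt(settings$g)
  attr(zfs, "uncertainty") <- c(d_ghz = geff * lw / 4 / 2,
                                e_ghz = geff * sqrt(2) * lw / 12 / 2)
  zfs
}
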