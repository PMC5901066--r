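## Orienting the zero-field frame in the molecular frame. The measured
## double-resonance spectra are orientation-selected relative to the
## zero-field axes, while supplied (e.g. DFT-derived) hyperfine tensors live
## in the molecular frame; a brute-force Euler-angle scan finds the rotation
## that lets the tensor set reproduce (1) the effective couplings at the
## D_zz edge and (2) the ENDOR spectrum at the D_yy position. Because
## A_eff depends on the field direction only through a quadratic form, the
## score is invariant under sign flips of the zero-field axes; solutions are
## reported as that symmetry orbit.

#' Tensor set
#'
#' A collection of [hyperfine_tensor()]s with unique nucleus identities and
#' a source tag.
#'
#' @param tensors List of [hyperfine_tensor()].
#' @param source Provenance tag, e.g. `"dft_GO"`, `"dft_CD_NH"`,
#'   `"synthetic"`.
#' @return Object of class `tensor_set`.
#' @export
tensor_set <- function(tensors, source = "synthetic") {
  stopifnot(is.list(tensors), length(tensors) >= 1L,
            all(vapply(tensors, inherits, logical(1), "hyperfine_tensor")))
  ids <- vapply(tensors, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate nucleus identities: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(tensors) <- ids
  structure(list(tensors = tensors, source = source), class = "tensor_set")
}

#' @export
print.tensor_set <- function(x, ...) {
  cat(sprintf("<tensor_set> %d nuclei (source: %s)\n", length(x$tensors),
              x$source))
  for (t in x$tensors) print(t)
  invisible(x)
}

#' Symmetrize a hyperfine tensor
#'
#' Makes the dipolar part axial by averaging T_xx and T_yy, leaving T_zz and
#' A_iso unchanged (the trace stays zero). Idempotent.
#'
#' @param hft [hyperfine_tensor()].
#' @return [hyperfine_tensor()] with axial dipolar part.
#' @examples
#' h <- hyperfine_tensor("1H", 0, c(-1, -3, 4))
#' symmetrize_tensor(h)$t_principal  # (-2, -2, 4)
#' @export
symmetrize_tensor <- function(hft) {
  stopifnot(inherits(hft, "hyperfine_tensor"))
  t <- hft$t_principal
  txy <- (t[1] + t[2]) / 2
  hyperfine_tensor(hft$nucleus, hft$a_iso_mhz, c(txy, txy, t[3]),
                   frame = hft$frame, id = hft$id, quad = hft$quad)
}

#' Adjust isotropic couplings toward measured components
#'
#' Shifts each assigned nucleus's A_iso so its predicted effective coupling
#' matches the measured one, clamped to `max_shift_mhz`. Mirrors the small
#' manual corrections applied to theory tensors when their dipolar parts are
#' trusted but the isotropic parts are slightly off.
#'
#' @param tensors [tensor_set()].
#' @param measured_aeff Named numeric: measured A_eff (MHz) keyed by nucleus
#'   identity.
#' @param direction Unit field direction (molecular frame) at which the
#'   couplings were measured (default the molecular z-axis).
#' @param max_shift_mhz Clamp on each |shift| (default 0.5 MHz); exceeding
#'   it triggers a warning and the clamped value is used.
#' @return [tensor_set()] with adjusted A_iso; attribute `"shifts"` records
#'   the applied shift per nucleus.
#' @export
adjust_aiso <- function(tensors, measured_aeff, direction = c(0, 0, 1),
                        max_shift_mhz = 0.5) {
  stopifnot(inherits(tensors, "tensor_set"), is.numeric(measured_aeff),
            !is.null(names(measured_aeff)))
  miss <- setdiff(names(measured_aeff), names(tensors$tensors))
  if (length(miss)) stop("no tensor for assigned nuclei: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  shifts <- numeric(0)
  out <- tensors$tensors
  for (id in names(measured_aeff)) {
    hft <- out[[id]]
    pred <- effective_coupling(hft, direction)$a_eff_mhz
    shift <- measured_aeff[[id]] - pred
    if (abs(shift) > max_shift_mhz) {
      warning(sprintf("A_iso shift for %s (%.2f MHz) exceeds clamp %.2f MHz; clamped",
                      id, shift, max_shift_mhz), call. = FALSE)
      shift <- sign(shift) * max_shift_mhz
    }
    out[[id]] <- hyperfine_tensor(hft$nucleus, hft$a_iso_mhz + shift,
                                  hft$t_principal, frame = hft$frame,
                                  id = hft$id, quad = hft$quad)
    shifts[id] <- shift
  }
  res <- tensor_set(out, source = tensors$source)
  attr(res, "shifts") <- shifts
  res
}

## ZYZ Euler angles from a rotation matrix (inverse of euler_matrix)
.matrix_to_euler <- function(r) {
  beta <- acos(max(-1, min(1, r[3, 3])))
  if (sin(beta) > 1e-9) {
    alpha <- atan2(r[2, 3], r[1, 3])
    gamma <- atan2(r[3, 2], -r[3, 1])
  } else {
    alpha <- atan2(r[2, 1], r[1, 1])
    gamma <- 0
  }
  euler_angles(alpha, beta, gamma)
}

#' Symmetry orbit of a zero-field frame
#'
#' The score of the Euler search depends on the zero-field axes only through
#' quadratic forms, so flipping the sign of any two axes (a proper 180-degree
#' rotation about the third) gives an equivalent frame. Returns the four
#' equivalent Euler triples.
#'
#' @param eul [euler_angles()].
#' @return List of four [euler_angles()], the first being the input.
#' @export
zfs_frame_orbit <- function(eul) {
  r <- euler_matrix(eul)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lapply(signs, function(s) .matrix_to_euler(r %*% diag(s)))
}

#' Predict search constraints for a candidate frame
#'
#' For a candidate rotation carrying the zero-field axes into the molecular
#' frame, computes (1) the effective coupling of every nucleus with the
#' field along the candidate D_zz axis (the low-field-edge ELDOR-NMR
#' observables) and (2) the proton ENDOR spectrum with the field along the
#' candidate D_yy axis, as Gaussian lines convolved to 150 kHz, restricted
#' to the -10 to -5 MHz window.
#'
#' @param tensors [tensor_set()].
#' @param euler [euler_angles()] (zero-field principal axes -> molecular
#'   frame; columns of [euler_matrix()] are D_xx, D_yy, D_zz).
#' @param manifolds Manifolds contributing to the ENDOR lines.
#' @param window ENDOR comparison window, MHz.
#' @param axis_step ENDOR axis step, MHz.
#' @param conv_width_mhz Gaussian FWHM of the ENDOR convolution (default
#'   0.150 MHz).
#' @return List with `aeff_zz` (named numeric per nucleus) and `endor_yy`
#'   ([spectrum_1d()] over the window).
#' @export
predict_constraints <- function(tensors, euler,
                                manifolds = c(-5/2, -3/2),
                                window = c(-10, -5), axis_step = 0.05,
                                conv_width_mhz = 0.150) {
  stopifnot(inherits(tensors, "tensor_set"), inherits(euler, "euler_angles"))
  r <- euler_matrix(euler)
  n_zz <- r[, 3]; n_yy <- r[, 2]
  aeff_zz <- vapply(tensors$tensors, function(h)
    effective_coupling(h, n_zz)$a_eff_mhz, numeric(1))
  protons <- Filter(function(h) h$nucleus == "1H", tensors$tensors)
  comps <- lapply(protons, function(h) {
    a <- effective_coupling(h, n_yy)$a_eff_mhz
    spectral_component(a, conv_width_mhz, 1, nucleus = "1H",
                       manifolds = manifolds, id = h$id)
  })
  axis <- seq(window[1], window[2], by = axis_step)
  endor <- suppressWarnings(
    synthesize_spectrum(comps, axis, kind = "endor"))
  list(aeff_zz = aeff_zz, endor_yy = endor)
}

## Gaussian mixture amplitudes on an axis, vectorized over rows of a
## position matrix (nrow cases x nlines); returns cases x length(axis)
.gauss_rows <- function(pos, intens, axis, sigma) {
  out <- matrix(0, nrow(pos), length(axis))
  for (j in seq_along(axis)) {
    e <- exp(-(axis[j] - pos)^2 / (2 * sigma^2))
    out[, j] <- drop(e %*% intens)
  }
  out
}

#' Brute-force Euler-angle search for the zero-field frame
#'
#' Exhaustive scan of (alpha, beta, gamma) on a regular grid. The score is
#' `w1 * RMS(A_eff mismatch) / rms(target couplings) + w2 * RMS(spectral
#' residual in the window) / rms(target spectrum)`. The coupling term
#' depends only on (alpha, beta) (the D_zz direction), which is exploited
#' both for speed and for an exact branch-and-bound: spectra are only
#' evaluated for (alpha, beta) cells whose coupling term alone cannot be
#' beaten. Deterministic; ties break to the smallest (beta, alpha, gamma).
#'
#' @param tensors [tensor_set()].
#' @param targets List with `aeff_zz` (named numeric; names must exist in
#'   the tensor set) and `endor_yy` ([spectrum_1d()] over the comparison
#'   window, e.g. from [predict_constraints()]).
#' @param grid_step_deg Grid step in degrees; must divide 360.
#' @param weights Length-2 `c(w1, w2)` for the coupling and spectral terms.
#' @param refine If `TRUE` (default) a 1-degree local pass around the best
#'   cell follows the coarse scan.
#' @param store_landscape If `TRUE`, return the full table of per-cell score
#'   terms (forces evaluation of the spectral term everywhere; slower).
#' @param manifolds,conv_width_mhz Passed to the ENDOR forward model (must
#'   match how `targets$endor_yy` was produced).
#' @param search_width_mhz Internal comparison width for the spectral term.
#'   At the display convolution of 150 kHz the spectral residual
#'   decorrelates within a fraction of a degree, which no practical grid
#'   can sample; the search therefore compares target and model broadened
#'   to this width (default 2 MHz), which makes the score basin a few
#'   degrees wide. The target spectrum is re-convolved with the
#'   complementary kernel, so the comparison is exact for in-window lines.
#' @return Object of class `frame_search_result`: list with `best`
#'   ([euler_angles()]), `score`, `grid_step_deg`, `solutions` (the symmetry
#'   orbit of `best`), `terms` (the two unweighted score terms at the
#'   optimum) and optionally `landscape`.
#' @export
euler_grid_search <- function(tensors, targets, grid_step_deg = 5,
                              weights = c(1, 1), refine = TRUE,
                              store_landscape = FALSE,
                              manifolds = c(-5/2, -3/2),
                              conv_width_mhz = 0.150,
                              search_width_mhz = 2.0) {
  stopifnot(inherits(tensors, "tensor_set"),
            is.list(targets), !is.null(targets$aeff_zz),
            !is.null(targets$endor_yy),
            360 %% grid_step_deg == 0, length(weights) == 2L)
  miss <- setdiff(names(targets$aeff_zz), names(tensors$tensors))
  if (length(miss)) stop("targets reference nuclei missing from the tensor ",
                         "set: ", paste(miss, collapse = ", "), call. = FALSE)
  step <- grid_step_deg * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- seq(0, 2 * pi - step / 2, by = step)
  res <- .search_grid(tensors, targets, alphas, betas, gammas, weights,
                      manifolds, conv_width_mhz, search_width_mhz,
                      store_landscape)
  if (refine && grid_step_deg > 1) {
    fine <- pi / 180
    # local 1-degree passes around the few best coarse cells (shallow or
    # near-degenerate landscapes can rank basins incorrectly at the coarse
    # step); each seed is re-centered while its optimum keeps improving
    seeds <- res$top
    for (si in seq_len(nrow(seeds))) {
      if (res$score < 0.02) break  # target essentially reproduced
      cur <- list(alpha = seeds$alpha[si], beta = seeds$beta[si],
                  gamma = seeds$gamma[si], score = seeds$score[si])
      for (pass in 1:6) {
        al <- cur$alpha + seq(-step, step, by = fine)
        be <- pmin(pi, pmax(0, cur$beta + seq(-step, step, by = fine)))
        ga <- cur$gamma + seq(-step, step, by = fine)
        res2 <- .search_grid(tensors, targets, al, unique(be), ga, weights,
                             manifolds, conv_width_mhz, search_width_mhz,
                             FALSE)
        if (res2$score >= cur$score - 1e-12) break
        cur <- list(alpha = res2$best$alpha, beta = res2$best$beta,
                    gamma = res2$best$gamma, score = res2$score)
        if (res2$score < res$score) {
          res$best <- res2$best; res$score <- res2$score
          res$terms <- res2$terms
        }
      }
    }
  }
  structure(list(best = res$best, score = res$score,
                 grid_step_deg = grid_step_deg,
                 solutions = zfs_frame_orbit(res$best),
                 terms = res$terms,
                 landscape = res$landscape),
            class = "frame_search_result")
}

#' @export
print.frame_search_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("<frame_search_result> best (alpha, beta, gamma) = (%.1f, %.1f, %.1f) deg, score = %.4g\n",
              b$alpha * 180 / pi, b$beta * 180 / pi, b$gamma * 180 / pi,
              x$score))
  cat(sprintf("  terms: couplings RMS %.4g, spectrum RMS %.4g (normalized)\n",
              x$terms[1], x$terms[2]))
  cat(sprintf("  %d symmetry-equivalent solutions (axis-sign orbit)\n",
              length(x$solutions)))
  invisible(x)
}

.search_grid <- function(tensors, targets, alphas, betas, gammas, weights,
                         manifolds, conv_width_mhz, search_width_mhz,
                         store_landscape) {
  tgt_a <- targets$aeff_zz
  ids <- names(tgt_a)
  tmats <- lapply(tensors$tensors[ids], dipolar_molframe)
  aisos <- vapply(tensors$tensors[ids], `[[`, numeric(1), "a_iso_mhz")
  norm_a <- sqrt(mean(tgt_a^2))
  spec_t <- targets$endor_yy
  axis <- spec_t$axis
  y_t <- spec_t$amplitude
  # broaden the window-truncated target to the search width with the
  # complementary kernel and subsample; the model is synthesized at the
  # display width on the fine window axis and pushed through the SAME
  # truncated broadening operator, so out-of-window lines drop out of both
  # sides of the comparison identically
  sw <- max(search_width_mhz, conv_width_mhz)
  dx <- axis[2] - axis[1]
  keep <- seq(1L, length(axis), by = max(1L, round((sw / 8) / dx)))
  if (sw > conv_width_mhz) {
    ksig <- sqrt(sw^2 - conv_width_mhz^2) / (2 * sqrt(2 * log(2)))
    half <- max(1L, ceiling(4 * ksig / dx))
    kern <- exp(-((-half:half) * dx)^2 / (2 * ksig^2))
    kern <- kern / sum(kern)
    y_t <- stats::convolve(c(numeric(half), y_t, numeric(half)), rev(kern),
                           type = "open")[(2 * half + 1):(2 * half +
                                                            length(axis))]
    # zero-padded broadening operator evaluated at the kept points
    kmat <- vapply(keep, function(k) {
      v <- numeric(length(axis))
      idx <- (k - half):(k + half)
      ok <- idx >= 1 & idx <= length(axis)
      v[idx[ok]] <- kern[ok]
      v
    }, numeric(length(axis)))
  } else {
    kmat <- diag(length(axis))[, keep, drop = FALSE]
  }
  axis_fine <- axis
  y_t <- y_t[keep]
  norm_s <- sqrt(mean(y_t^2))
  if (norm_a == 0) norm_a <- 1
  if (norm_s == 0) norm_s <- 1
  sigma <- conv_width_mhz / (2 * sqrt(2 * log(2)))
  protons <- Filter(function(h) h$nucleus == "1H", tensors$tensors)
  pmats <- lapply(protons, dipolar_molframe)
  paisos <- vapply(protons, `[[`, numeric(1), "a_iso_mhz")
  nman <- length(manifolds)

  ab <- expand.grid(alpha = alphas, beta = betas)
  sa <- sin(ab$alpha); ca <- cos(ab$alpha)
  sb <- sin(ab$beta);  cb <- cos(ab$beta)
  n3 <- cbind(ca * sb, sa * sb, cb)
  qform <- function(n, m) rowSums((n %*% m) * n)
  mism2 <- 0
  for (k in seq_along(ids)) {
    mism2 <- mism2 + (qform(n3, tmats[[k]]) + aisos[k] - tgt_a[[k]])^2
  }
  t1 <- sqrt(mism2 / length(ids)) / norm_a
  w1 <- weights[1]; w2 <- weights[2]

  # frame x-, y-axis carriers: n2(gamma) = -sin(g) u + cos(g) v
  u <- cbind(ca * cb, sa * cb, -sb)
  v <- cbind(-sa, ca, numeric(length(sa)))
  quu <- sapply(pmats, function(m) qform(u, m))
  qvv <- sapply(pmats, function(m) qform(v, m))
  quv <- sapply(pmats, function(m) rowSums((u %*% m) * v))
  quu <- matrix(quu, ncol = length(pmats))
  qvv <- matrix(qvv, ncol = length(pmats))
  quv <- matrix(quv, ncol = length(pmats))

  sg <- sin(gammas); cg <- cos(gammas)
  eval_t2 <- function(i_ab) {
    # all gammas at one (alpha, beta): proton A_eff along the frame y-axis
    aeff <- outer(sg^2, quu[i_ab, ]) + outer(cg^2, qvv[i_ab, ]) -
      2 * outer(sg * cg, quv[i_ab, ])
    aeff <- sweep(aeff, 2, paisos, "+")
    # ENDOR: both branches, each manifold, equal weights
    pos <- NULL; intens <- NULL
    for (m in manifolds) {
      pos <- cbind(pos, -m * aeff, m * aeff)
      intens <- c(intens, rep(1 / nman, 2 * ncol(aeff)))
    }
    ymodel <- .gauss_rows(pos, intens, axis_fine, sigma) %*% kmat
    sqrt(rowMeans(sweep(ymodel, 2, y_t)^2)) / norm_s
  }

  best <- list(score = Inf)
  top <- NULL  # few best cells kept as refinement seeds
  land <- if (store_landscape) vector("list", nrow(ab)) else NULL
  ord <- order(t1)
  for (i in ord) {
    if (!store_landscape && w1 * t1[i] >= best$score) break
    t2g <- eval_t2(i)
    sc <- w1 * t1[i] + w2 * t2g
    j <- which.min(sc)
    # refinement seeds: the best gamma in this cell plus the best gamma
    # well separated from it modulo pi (the spectral term is invariant
    # under gamma -> gamma + pi, so the half-circle is the real period;
    # nearby basins can be ranked incorrectly at the coarse step)
    og <- order(sc)
    ng <- length(gammas)
    d_full <- pmin(abs(og - j), ng - abs(og - j))
    d_half <- pmin(d_full, abs(d_full - ng / 2))
    far <- og[which(d_half > 1L)[1]]
    jj <- c(j, far[!is.na(far)])
    top <- rbind(top, data.frame(score = sc[jj], alpha = ab$alpha[i],
                                 beta = ab$beta[i], gamma = gammas[jj]))
    if (nrow(top) > 8L) top <- top[order(top$score)[1:8], ]
    # tie-break: smallest (beta, alpha, gamma)
    if (sc[j] < best$score - 1e-12 ||
        (abs(sc[j] - best$score) <= 1e-12 &&
         .lex_less(c(ab$beta[i], ab$alpha[i], gammas[j]),
                   c(best$beta, best$alpha, best$gamma)))) {
      best <- list(score = sc[j], alpha = ab$alpha[i], beta = ab$beta[i],
                   gamma = gammas[j], t1 = t1[i], t2 = t2g[j])
    }
    if (store_landscape) {
      land[[i]] <- data.frame(alpha = ab$alpha[i], beta = ab$beta[i],
                              gamma = gammas, t1 = t1[i], t2 = t2g,
                              score = sc)
    }
  }
  list(best = euler_angles(best$alpha, best$beta, best$gamma),
       score = best$score, terms = c(couplings = best$t1,
                                     spectrum = best$t2),
       top = top[order(top$score), , drop = FALSE],
       landscape = if (store_landscape) do.call(rbind, land) else NULL)
}
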