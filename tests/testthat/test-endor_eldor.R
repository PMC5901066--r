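test_that("single-quantum line positions follow the offset convention", {
  # matrix line: zero coupling, single line at zero offset
  ll0 <- sq_frequencies(0, "1H", -5/2)
  expect_equal(ll0$offset_mhz, 0)

  # the two resolved features: 5.3 MHz through -3/2 -> 7.95 MHz,
  # 6.4 MHz through -5/2 -> 16.0 MHz
  expect_equal(max(sq_frequencies(5.3, "1H", -3/2)$offset_mhz), 7.95)
  expect_equal(max(sq_frequencies(6.4, "1H", -5/2)$offset_mhz), 16.0)
  # both branches, symmetric about zero
  ll <- sq_frequencies(6.4, "1H", -5/2)
  expect_equal(sort(ll$offset_mhz), c(-16, 16))

  # I = 1 with zero quadrupole projection reduces to the I = 1/2 positions
  ll_n <- sq_frequencies(4, "14N", -5/2, p_eff_mhz = 0)
  expect_equal(sort(unique(ll_n$offset_mhz)), c(-10, 10))
  # nonzero P_eff splits each branch by +/- 3/2 P_eff
  ll_q <- sq_frequencies(4, "14N", -5/2, p_eff_mhz = 0.4)
  expect_equal(sort(ll_q$offset_mhz), c(-10.6, -9.4, 9.4, 10.6))

  expect_error(sq_frequencies(4, "1H", -5/2, p_eff_mhz = 0.4), "spin-1/2")
})

test_that("multiple-quantum combination offsets sum participant flips", {
  # single 14N double-quantum: A_eff = 4 -> 20 MHz at -5/2, 12 MHz at -3/2
  n_dq <- function(ms) mq_frequencies(
    data.frame(a_eff_mhz = 4, nucleus = "14N", dm_i = 2), ms)
  expect_equal(n_dq(-5/2)$offset_mhz, 20)
  expect_equal(n_dq(-3/2)$offset_mhz, 12)

  # two water protons at -5/2: 2.5 * (6.4 + 5.3) = 29.25 MHz
  two_h <- mq_frequencies(data.frame(a_eff_mhz = c(6.4, 5.3),
                                     nucleus = "1H", dm_i = c(1, 1)), -5/2)
  expect_equal(two_h$offset_mhz, 29.25)
  expect_equal(attr(two_h, "q"), 2)

  # a zero-coupling participant contributes nothing
  with0 <- mq_frequencies(data.frame(a_eff_mhz = c(6.4, 0),
                                     nucleus = "1H", dm_i = c(1, 1)), -5/2)
  expect_equal(with0$offset_mhz, 16)

  expect_error(mq_frequencies(data.frame(a_eff_mhz = 1, nucleus = "1H",
                                         dm_i = 2), -5/2), "exceeds 2I")
  expect_error(mq_frequencies(data.frame(a_eff_mhz = 1, nucleus = "1H",
                                         dm_i = 1), -5/2), "q = sum")
})

test_that("offset-to-coupling inversion matches the reported conversions", {
  # the observed low edge: -12.0 MHz at (q = 1, ms = -5/2) -> -4.8 MHz
  expect_equal(offset_to_aeff(-12.0, -5/2, 1), -4.8)
  expect_equal(offset_to_aeff(4.7, -5/2, 1), 1.88)
  # the 14N DQ doublet: both members give the same 4 MHz coupling
  expect_equal(offset_to_aeff(20, -5/2, 2), 4.0)
  expect_equal(offset_to_aeff(12, -3/2, 2), 4.0)
  expect_error(offset_to_aeff(1, -5/2, 0), "nonzero")

  # forward/inverse consistency over random couplings
  set.seed(4)
  for (i in 1:50) {
    a <- runif(1, -8, 8); ms <- sample(c(-5/2, -3/2, 1/2, 3/2), 1)
    off <- max(sq_frequencies(a, "1H", ms)$offset_mhz * sign(-ms * a))
    off <- -ms * a  # positive-branch offset
    expect_equal(offset_to_aeff(off, ms, 1), a, tolerance = 1e-12)
  }
})

test_that("round trip through effective_coupling offsets", {
  set.seed(9)
  for (i in 1:20) {
    h <- hyperfine_tensor("1H", runif(1, -1, 1),
                          t_to_principal(runif(1, 1, 5)),
                          frame = euler_angles(runif(1, 0, 6),
                                               runif(1, 0, pi), 0))
    n <- direction_from_angles(acos(runif(1, -1, 1)), runif(1, 0, 6))
    q <- sample(1:3, 1); ms <- sample(c(-5/2, -3/2, 3/2), 1)
    ec <- effective_coupling(h, n, ms, q)
    expect_equal(offset_to_aeff(ec$offset_mhz, ms, q), ec$a_eff_mhz,
                 tolerance = 1e-12)
  }
})

test_that("synthesized spectra place and scale Gaussian components", {
  ax <- seq(-2, 20, by = 0.02)
  one <- list(spectral_component(5.0, 2.0, manifolds = -5/2))
  sp <- synthesize_spectrum(one, ax, "eldor_sq")
  expect_equal(ax[which.max(sp$amplitude)], 12.5, tolerance = 0.05)
  half <- max(sp$amplitude) / 2
  expect_equal(diff(range(ax[sp$amplitude >= half])), 2.0, tolerance = 0.1)

  # two components through two manifolds: resolved maxima near 8 and 16
  ax2 <- seq(-6, 28, by = 0.05)
  comps <- list(spectral_component(5.3, 2.2), spectral_component(6.4, 2.2))
  sp2 <- synthesize_spectrum(comps, ax2, "eldor_sq")
  pk <- ax2[hfepr:::.local_maxima(sp2$amplitude)]
  expect_true(any(abs(pk - 16) < 0.5))
  expect_true(any(abs(pk - 8) < 1.0))

  # linear amplitude scaling
  comps3 <- list(spectral_component(5.3, 2.2, amplitude = 3),
                 spectral_component(6.4, 2.2, amplitude = 3))
  sp3 <- synthesize_spectrum(comps3, ax2, "eldor_sq")
  expect_equal(sp3$amplitude, 3 * sp2$amplitude, tolerance = 1e-9)

  # ENDOR kind carries both branches
  spe <- synthesize_spectrum(one, seq(-20, 20, 0.02), "endor")
  expect_equal(spe$amplitude, rev(spe$amplitude), tolerance = 1e-9)

  expect_warning(synthesize_spectrum(one, seq(-2, 13, 0.02), "eldor_sq"),
                 "clipped")
})

test_that("component fits recover generator components", {
  ax <- seq(-6, 28, by = 0.05)
  comps <- list(spectral_component(5.3, 2.2), spectral_component(6.4, 2.2))
  sp <- synthesize_spectrum(comps, ax, "eldor_sq")
  fit <- fit_components(sp, 2)
  a <- vapply(fit, `[[`, numeric(1), "a_eff_mhz")
  expect_equal(a, c(5.3, 6.4), tolerance = 0.05)
  expect_lt(attr(fit, "residual") / max(sp$amplitude), 1e-4)

  # a third weak component (the 2.6 MHz shoulder of the inactive protein)
  comps3 <- list(spectral_component(2.6, 2.2, amplitude = 0.6),
                 spectral_component(5.3, 2.2), spectral_component(6.4, 2.2))
  sp3 <- synthesize_spectrum(comps3, ax, "eldor_sq")
  fit3 <- fit_components(sp3, 3)
  a3 <- vapply(fit3, `[[`, numeric(1), "a_eff_mhz")
  expect_equal(a3[1], 2.6, tolerance = 0.1)
  expect_equal(a3[2:3], c(5.3, 6.4), tolerance = 0.1)

  # seeded noise at SNR 20 moves the recovered couplings by < 0.2 MHz
  for (sd in 1:5) {
    spn <- add_noise(sp, 20, seed = sd)
    fn <- fit_components(spn, 2)
    an <- vapply(fn, `[[`, numeric(1), "a_eff_mhz")
    expect_lt(max(abs(an - c(5.3, 6.4))), 0.2)
  }
})

test_that("DQ edges implement the pairwise sum rule", {
  comps <- list(spectral_component(6.4, 2.2), spectral_component(5.3, 2.2))
  expect_equal(dq_edges(comps, -5/2)[["high_mhz"]], 29.25)
  # the alternative reading: two protons sharing A_eff = 6.4
  same <- list(spectral_component(6.4, 2.2), spectral_component(6.4, 2.2))
  expect_equal(dq_edges(same, -5/2)[["high_mhz"]], 32.0)
  # degenerate component set
  zero <- list(spectral_component(0, 1))
  expect_equal(unname(dq_edges(zero, -5/2)), c(0, 0))

  # exact identity: high edge equals the sum of the two largest SQ
  # positive-branch offsets at the same manifold
  set.seed(14)
  for (i in 1:25) {
    a <- runif(sample(2:5, 1), -4, 8)
    cl <- lapply(a, spectral_component, width_mhz = 1)
    for (ms in c(-5/2, -3/2)) {
      sq_off <- vapply(a, function(ai)
        max(sq_frequencies(ai, "1H", ms)$offset_mhz), numeric(1))
      sq_off <- -ms * a  # positive-branch offsets (signed)
      top2 <- sort(sq_off, decreasing = TRUE)[1:2]
      expect_equal(dq_edges(cl, ms)[["high_mhz"]], sum(top2),
                   tolerance = 1e-12)
    }
  }
})

test_that("single-nucleus 14N DQ lines ignore the quadrupole tensor", {
  set.seed(16)
  base <- NULL
  for (i in 1:100) {
    p <- runif(2, -1, 1)
    quad <- quadrupole_tensor(c(p, -sum(p)),
                              euler_angles(runif(1, 0, 6),
                                           runif(1, 0, pi), 0))
    h <- hyperfine_tensor("14N", 3, c(-0.5, -0.5, 1), quad = quad)
    # SQ lines move with the quadrupole ...
    n <- c(0, 0, 1)
    sq <- sq_frequencies(effective_coupling(h, n)$a_eff_mhz, "14N", -5/2,
                         quad = quad, direction = n)
    # ... but the one-nucleus DQ line is purely hyperfine-determined
    dq <- mq_frequencies(data.frame(
      a_eff_mhz = effective_coupling(h, n)$a_eff_mhz,
      nucleus = "14N", dm_i = 2), -5/2)
    if (is.null(base)) base <- dq$offset_mhz
    expect_identical(dq$offset_mhz, base)
  }
})

test_that("forbiddenness weights are normalized and decay with q", {
  w <- eldor_forbiddenness(c(1, 2, 4), 79, q = 1)
  expect_equal(max(w), 1)
  expect_true(all(diff(w) > 0))
  w2 <- eldor_forbiddenness(2, 79, q = 2)
  expect_lt(w2 * (2 / 79)^0, 1 + 1e-12)
})
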