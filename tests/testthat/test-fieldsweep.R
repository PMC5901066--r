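settings6 <- spectrometer_settings(94, 2.0023, 6)

test_that("powder grid weights are normalized solid-angle weights", {
  g <- make_powder_grid(2, 2)
  expect_length(g$theta, 4L)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)

  g2 <- make_powder_grid(90, 10)
  # equatorial band outweighs polar band for equal Delta theta
  polar <- sum(g2$weights[g2$theta < 10 * pi / 180])
  equat <- sum(g2$weights[g2$theta > 80 * pi / 180])
  expect_gt(equat, polar)
  # integral of the constant function 1 is 1
  expect_equal(sum(g2$weights * 1), 1, tolerance = 1e-12)
})

test_that("near-isotropic limit gives a single Gaussian at the center", {
  z <- zfs_parameters(1e-6, 0)
  ax <- seq(3254, 3454, by = 1)
  sp <- simulate_fieldsweep(settings6, z, field_axis = ax, linewidth_mt = 10)
  expect_equal(sp$axis[which.max(sp$amplitude)], center_field(settings6),
               tolerance = 1)
  # FWHM matches the linewidth
  half <- max(sp$amplitude) / 2
  xs <- range(sp$axis[sp$amplitude >= half])
  expect_equal(diff(xs), 10, tolerance = 1.5)
})

test_that("simulated pattern edges sit at the canonical turning points", {
  z <- zfs_parameters(-10.60, 0.63)
  sp <- simulate_fieldsweep(settings6, z, transitions = c(-5/2, -3/2))
  cp <- canonical_positions(settings6, z)
  zz <- cp$positions$field_mt[cp$positions$axis == "zz" &
                                cp$positions$ms == -5/2]
  # extreme low-field shoulder within one linewidth of (zz, -5/2)
  onset <- min(sp$axis[sp$amplitude >= 0.05 * max(sp$amplitude)])
  expect_lt(abs(onset - zz), 10)

  # amplitude scale invariance of the located turning points
  sp2 <- spectrum_1d(sp$axis, 2 * sp$amplitude, kind = "fieldsweep",
                     meta = sp$meta)
  tp1 <- locate_turning_points(sp, settings6)
  tp2 <- locate_turning_points(sp2, settings6)
  expect_equal(tp1$positions$field_mt, tp2$positions$field_mt)
})

test_that("narrow axis warns about clipping", {
  z <- zfs_parameters(-10.60, 0.63)
  expect_warning(
    simulate_fieldsweep(settings6, z, field_axis = seq(3000, 3700, 2),
                        transitions = c(-5/2, -3/2)),
    "clipped")
})

test_that("located turning points match the canonical ones on synthetics", {
  z <- zfs_parameters(-10.66, 0.43)  # cambialistic-protein parameters
  sp <- simulate_fieldsweep(settings6, z, transitions = c(-5/2, -3/2))
  tp <- locate_turning_points(sp, settings6)
  cp <- canonical_positions(settings6, z)
  for (i in seq_len(nrow(tp$positions))) {
    want <- cp$positions$field_mt[
      cp$positions$axis == tp$positions$axis[i] &
        cp$positions$ms == tp$positions$ms[i]]
    expect_lt(abs(tp$positions$field_mt[i] - want), 5)  # half a linewidth
  }
  # supplying the sign via a guess gives the same assignment
  tpg <- locate_turning_points(sp, settings6, zfs_guess = z)
  expect_equal(tpg$positions$field_mt, tp$positions$field_mt)
})

test_that("degenerate spectra are rejected with informative errors", {
  set.seed(1)
  ax <- seq(1700, 4500, by = 2)
  noise <- spectrum_1d(ax, rnorm(length(ax)), kind = "fieldsweep")
  expect_error(locate_turning_points(noise, settings6, linewidth_mt = 10),
               "turning-point|features")
})

test_that("axis shifts translate the located turning points", {
  z <- zfs_parameters(-10.60, 0.63)
  sp <- simulate_fieldsweep(settings6, z, transitions = c(-5/2, -3/2))
  sp_shift <- spectrum_1d(sp$axis + 2, sp$amplitude, kind = "fieldsweep",
                          meta = sp$meta)
  tp <- locate_turning_points(sp, settings6)
  tps <- locate_turning_points(sp_shift, settings6)
  expect_equal(tps$positions$field_mt, tp$positions$field_mt + 2,
               tolerance = 2.5)  # one axis step of slack
})

test_that("extract_zfs recovers generator parameters", {
  # Mn-specific protein parameters, 10 mT linewidth
  z <- zfs_parameters(-10.60, 0.63)
  sp <- simulate_fieldsweep(settings6, z, transitions = c(-5/2, -3/2))
  zh <- extract_zfs(sp, settings6)
  expect_equal(zh$d_ghz, -10.60, tolerance = 0.15)
  expect_equal(zh$e_ghz, 0.63, tolerance = 0.1)
  expect_true(all(attr(zh, "uncertainty") > 0))

  # inactive-protein parameters satisfy the |D| + E <= 10.9 GHz bound
  zfe <- zfs_parameters(-10.46, 0.33)
  spfe <- simulate_fieldsweep(settings6, zfe, transitions = c(-5/2, -3/2))
  zhfe <- extract_zfs(spfe, settings6)
  expect_lte(abs(zhfe$d_ghz) + zhfe$e_ghz, 10.9)

  # (near-)axial generator recovers E ~ 0
  zax <- zfs_parameters(-10.5, 1e-4)
  spax <- simulate_fieldsweep(settings6, zax, transitions = c(-5/2, -3/2))
  zhax <- extract_zfs(spax, settings6)
  expect_lt(zhax$e_ghz, 0.06)
})

test_that("extraction works on the default five-transition simulation", {
  z <- zfs_parameters(-10.60, 0.63)
  sp <- simulate_fieldsweep(settings6, z)  # all five transitions, 6 K
  zh <- extract_zfs(sp, settings6)
  expect_equal(zh$d_ghz, -10.60, tolerance = 0.2)
  expect_equal(zh$e_ghz, 0.63, tolerance = 0.1)
})

test_that("parameter recovery holds across the SOD regime (spot sample)", {
  # the full 50-draw suite runs in the acceptance tests; this is a fast
  # 8-draw version exercising the same property
  set.seed(21)
  for (i in 1:8) {
    d <- -runif(1, 9, 12)
    e <- min(runif(1, 0, 1), abs(d) / 3 - 1e-3)
    z <- zfs_parameters(d, e)
    sp <- simulate_fieldsweep(settings6, z, transitions = c(-5/2, -3/2))
    zh <- extract_zfs(sp, settings6)
    expect_lt(abs(zh$d_ghz - d) / abs(d), 0.02)
    expect_lt(abs(zh$e_ghz - e), 0.1)
  }
})

test_that("integrated amplitude is invariant under grid refinement", {
  z <- zfs_parameters(-10.60, 0.63)
  ax <- seq(1750, 4350, by = 2)
  int_of <- function(n_th, n_ph) {
    sp <- simulate_fieldsweep(settings6, z,
                              grid = make_powder_grid(n_th, n_ph),
                              field_axis = ax,
                              transitions = c(-5/2, -3/2))
    sum(sp$amplitude) * 2
  }
  i1 <- int_of(180, 90)
  i2 <- int_of(361, 181)
  expect_lt(abs(i1 - i2) / i2, 0.005)
})
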