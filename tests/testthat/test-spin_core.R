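test_that("first-order shift closed form reproduces canonical values", {
  z <- zfs_parameters(-10.60, 0.63)

  # axial term vanishes at the magic angle when E = 0
  zax <- zfs_parameters(-10.60, 0)
  magic <- acos(sqrt(1 / 3))
  expect_equal(firstorder_shift(zax, orientation(magic, 1.23), -5/2), 0,
               tolerance = 1e-12)

  # field along D_zz for the -5/2 manifold: (-2) * 2D
  expect_equal(firstorder_shift(z, orientation(0), -5/2), 42.40,
               tolerance = 1e-10)

  # equatorial, phi = pi/2: (-2) * (-D - 3E) = -17.42 GHz by direct
  # evaluation (and confirmed by the exact oracle below)
  expect_equal(firstorder_shift(z, orientation(pi/2, pi/2), -5/2), -17.42,
               tolerance = 1e-10)

  expect_error(firstorder_shift(z, orientation(0), 5/2), "ms must be")
})

test_that("equatorial sweep attains extremes -D + 3E and -D - 3E exactly", {
  z <- zfs_parameters(-11.2, 0.8)
  phis <- seq(0, 2 * pi, length.out = 721)
  vals <- vapply(phis, function(p)
    firstorder_shift(z, orientation(pi/2, p), -3/2), numeric(1))
  # ms = -3/2 multiplies the bracket by -1
  expect_equal(max(vals), -(-z$d_ghz - 3 * z$e_ghz), tolerance = 1e-9)
  expect_equal(min(vals), -(-z$d_ghz + 3 * z$e_ghz), tolerance = 1e-9)
})

test_that("resonance field: center value, symmetry and error branch", {
  s <- spectrometer_settings(94, 2.0023, 6)
  # isotropic limit: nu h / (g beta) from CODATA constants
  ztiny <- zfs_parameters(1e-9, 0)
  expect_equal(resonance_field(s, ztiny, orientation(1, 1), -1/2),
               3354.19, tolerance = 1e-4)

  # shift s and -s average to the center field (E = 0, flip sign of D)
  o <- orientation(0.4, 1.1)
  zp <- zfs_parameters(8, 0); zm <- zfs_parameters(-8, 0)
  b1 <- resonance_field(s, zp, o, -5/2)
  b2 <- resonance_field(s, zm, o, -5/2)
  expect_equal((b1 + b2) / 2, center_field(s), tolerance = 1e-9)

  # unphysical: shift exceeding nu_obs
  expect_error(resonance_field(s, zfs_parameters(-50, 0), orientation(0),
                               -5/2),
               "unphysical")
})

test_that("canonical positions have the right geometry for negative D", {
  s <- spectrometer_settings()
  z <- zfs_parameters(-10.46, 0.33)  # inactive-protein parameters
  cp <- canonical_positions(s, z)
  b0 <- cp$center_mt
  get <- function(ax, ms) {
    p <- cp$positions
    p$field_mt[p$axis == ax & p$ms == ms]
  }
  expect_lt(get("zz", -5/2), b0)
  expect_gt(get("xx", -5/2), b0)
  expect_gt(get("yy", -5/2), b0)
  # four distinct read-off fields
  expect_equal(length(unique(round(cp$positions$field_mt, 6))), 6L)
  # (ms + 1/2) ratio: zz offset of -5/2 is twice that of -3/2
  expect_equal(get("zz", -5/2) - b0, 2 * (get("zz", -3/2) - b0),
               tolerance = 1e-9)
})

test_that("turning-point inversion round-trips (D, E) exactly", {
  s <- spectrometer_settings()
  for (de in list(c(-10.60, 0.63), c(-10.46, 0.33))) {
    z <- zfs_parameters(de[1], de[2])
    zr <- invert_turning_points(canonical_positions(s, z), s)
    expect_equal(zr$d_ghz, de[1], tolerance = 1e-10)
    expect_equal(zr$e_ghz, de[2], tolerance = 1e-10)
  }

  # 1000 random (D, E) in the convention: exact round-trip
  set.seed(11)
  for (i in 1:1000) {
    d <- sample(c(-1, 1), 1) * runif(1, 1, 15)
    e <- runif(1, 0, abs(d) / 3)
    z <- zfs_parameters(d, e)
    zr <- invert_turning_points(canonical_positions(s, z), s)
    expect_equal(zr$d_ghz, d, tolerance = 1e-9)
    expect_equal(zr$e_ghz, e, tolerance = 1e-9)
  }
})

test_that("rigid field-calibration shifts leave the read-off unchanged", {
  s <- spectrometer_settings()
  z <- zfs_parameters(-10.60, 0.63)
  cp <- canonical_positions(s, z)
  # shift all fields AND the center by +1 mT (a calibration offset)
  cp2 <- turning_point_set(transform(cp$positions,
                                     field_mt = field_mt + 1),
                           cp$center_mt + 1)
  zr <- invert_turning_points(cp2, s)
  expect_equal(zr$d_ghz, z$d_ghz, tolerance = 1e-9)
  expect_equal(zr$e_ghz, z$e_ghz, tolerance = 1e-9)
  # shifting only the four fields leaves E (a field difference) exact and
  # moves D by g beta/(4h) per mT
  cp3 <- turning_point_set(transform(cp$positions,
                                     field_mt = field_mt + 1),
                           cp$center_mt)
  zr3 <- invert_turning_points(cp3, s)
  expect_equal(zr3$e_ghz, z$e_ghz, tolerance = 1e-9)
  expect_equal(zr3$d_ghz - z$d_ghz, electron_ghz_per_mt(s$g) / 4,
               tolerance = 1e-9)
})

test_that("missing labels and out-of-convention recovery are flagged", {
  s <- spectrometer_settings()
  cp <- canonical_positions(s, zfs_parameters(-10.6, 0.63))
  cp$positions <- cp$positions[cp$positions$axis != "yy", ]
  expect_error(invert_turning_points(cp, s), "missing the read-off labels")

  # fields implying E/|D| > 1/3 warn and flag
  b0 <- center_field(s)
  geff <- electron_ghz_per_mt(s$g)
  tp <- turning_point_set(
    data.frame(axis = c("zz", "zz", "xx", "yy"),
               ms = c(-5/2, -3/2, -5/2, -5/2),
               field_mt = b0 + c(-4 * 2 / geff, -2 * 2 / geff,
                                 40 / geff, -40 / geff)),
    b0)
  expect_warning(zr <- invert_turning_points(tp, s), "exceeds 1/3")
  expect_true(isTRUE(attr(zr, "non_canonical")))
})

test_that("zfs canonicalization preserves principal values", {
  set.seed(3)
  pv_of <- function(d, e) sort(c(-d / 3 + e, -d / 3 - e, 2 * d / 3))
  for (i in 1:50) {
    d <- runif(1, -12, 12); if (abs(d) < 0.5) d <- 1
    e <- runif(1, -8, 8)
    ce <- canonicalize_zfs(d, e)
    expect_true(ce[2] >= 0 && ce[2] <= abs(ce[1]) / 3 + 1e-12)
    expect_equal(pv_of(ce[1], ce[2]), pv_of(d, e), tolerance = 1e-9)
  }
  # in-convention input is untouched
  z <- zfs_parameters(3, 2, canonicalize = TRUE)
  expect_true(z$e_ghz <= abs(z$d_ghz) / 3 + 1e-12)
  expect_error(zfs_parameters(3, 2), "convention")
})

test_that("Boltzmann weights are normalized and monotone at 6 K", {
  s <- spectrometer_settings(94, 2.0023, 6)
  ms_all <- seq(-5/2, 5/2)
  w <- boltzmann_weight(s, 3355, ms_all)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))  # decreasing in ms at positive field

  s_hot <- spectrometer_settings(94, 2.0023, 1e9)
  w_hot <- boltzmann_weight(s_hot, 3355, ms_all)
  expect_equal(w_hot, rep(1 / 6, 6), tolerance = 1e-6)
})

test_that("first-order shifts match exact diagonalization to second order", {
  # independent oracle: numerical eigenvalues of the 6x6 Hamiltonian at the
  # center field. The worst-case second-order coefficient for S = 5/2 in
  # the SOD regime (E/|D| <= 0.1) is just under 10/nu_obs, the bound used
  # here.
  s <- spectrometer_settings(94, 2.0023, 6)
  b0 <- center_field(s)
  set.seed(5)
  for (de in list(c(-10.60, 0.63), c(-10.46, 0.33), c(-9.0, 0.9))) {
    z <- zfs_parameters(de[1], de[2])
    bound <- 10 * z$d_ghz^2 / s$nu_obs_ghz
    for (k in 1:20) {
      th <- acos(runif(1, -1, 1)); ph <- runif(1, 0, 2 * pi)
      for (ms in c(-5/2, -3/2, -1/2, 1/2, 3/2)) {
        fo <- s$nu_obs_ghz + firstorder_shift(z, orientation(th, ph), ms)
        ex <- exact_transition_freq(b0, z$d_ghz, z$e_ghz, th, ph, ms, s$g)
        expect_lt(abs(ex - fo), bound)
      }
    }
  }
  # the oracle also confirms the sign of the equatorial example: the exact
  # -5/2 transition at (pi/2, pi/2) sits BELOW nu_obs for D = -10.60
  z <- zfs_parameters(-10.60, 0.63)
  ex <- exact_transition_freq(b0, z$d_ghz, z$e_ghz, pi/2, pi/2, -5/2, s$g)
  expect_lt(ex, s$nu_obs_ghz)
  expect_equal(ex - s$nu_obs_ghz, -17.42, tolerance = 2.5)
})

test_that("settings and zfs constructors validate their invariants", {
  expect_error(spectrometer_settings(g = 3), "1.5")
  expect_error(spectrometer_settings(temperature_k = -1))
  expect_error(zfs_parameters(0, 0), "nonzero")
  expect_error(orientation(4), "theta")
  expect_silent(orientation(1, 7))  # phi wrapped
})
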