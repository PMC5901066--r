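## Synthetic-data generator: idealized trigonal-bipyramidal Mn(II) active
## sites (three histidines, one aspartate, one water), hyperfine tensor sets
## built from them by the point-dipole model, and seeded noise. Crystal
## structures of these sites resolve no hydrogens, so protons are placed
## with standard covalent geometry (O-H 0.97 A, H-O-H 104.5 deg; ring C-H
## 1.08 A in-plane). The molecular frame convention is z along the
## Mn-N(His26) axial bond and x along the Mn-O(Asp167) equatorial bond.

## imidazole ring as a regular pentagon (side 1.37 A), attached through
## N_epsilon at distance d along unit vector u from the metal; the ring
## plane contains u and the vector w; flanking carbons at +/-72 deg carry
## the two in-plane ring protons (C-H 1.08 A, radial)
.imidazole_ring <- function(u, w, d_mn_n = 2.23) {
  side <- 1.37
  rad <- side / (2 * sin(pi / 5))
  centroid <- (d_mn_n + rad) * u
  at <- function(angle, radius) {
    centroid + radius * (cos(angle) * (-u) + sin(angle) * w)
  }
  list(n_e = at(0, rad),
       h2 = at(2 * pi / 5, rad + 1.08),
       h5 = at(-2 * pi / 5, rad + 1.08))
}

## rotate vector v about unit axis u by angle a (Rodrigues)
.rotate_about <- function(v, u, a) {
  v * cos(a) + pracma_cross(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a toy Mn(II) active site
#'
#' Constructs an idealized trigonal-bipyramidal site: His26 and water axial,
#' His81, His171 and Asp167 equatorial. The water protons are placed (by a
#' deterministic constrained optimization of the water tilt, Mn-O distance
#' and O-H length within standard-geometry bounds) so their Mn-H distances
#' come out near 2.62 and 2.91 A, the distances inferred for the two
#' water-ligand protons. The His171 ring dihedral relative to the
#' O_water-Mn-N_His26 axis distinguishes the variants: +30 degrees
#' (`"MnSOD_like"`, the crystal-structure arrangement) versus -60 degrees
#' (`"FeSOD_like"`, the rotated ring of the inactive protein).
#'
#' @param variant `"MnSOD_like"` or `"FeSOD_like"`.
#' @param seed Integer seed recorded in the site and used for the optional
#'   coordinate jitter.
#' @param jitter_sd Gaussian jitter (A) added to all non-metal coordinates;
#'   default 0 (exact idealized geometry).
#' @return Object of class `toy_site`: list with `coords` (matrix, rows
#'   named by atom), `variant`, `ring_dihedral_his171_deg`, `rng_seed`.
#' @examples
#' site <- build_toy_site("MnSOD_like")
#' round(sqrt(rowSums(site$coords^2)), 2)[c("H_wp", "H_w")]  # ~2.62, 2.91
#' @export
build_toy_site <- function(variant = c("MnSOD_like", "FeSOD_like"),
                           seed = 1L, jitter_sd = 0) {
  variant <- match.arg(variant)
  dihedral_deg <- if (variant == "MnSOD_like") 30 else -60
  d_mn_nax <- 2.23
  d_mn_neq <- 2.23
  d_mn_od <- 2.09

  ## water: O along -z; two H in the xz-plane; tilt chi of the water C2
  ## axis, Mn-O distance and O-H length optimized (within standard-geometry
  ## bounds) to reach Mn-H targets 2.62 / 2.91 A
  water_h <- function(par) {
    d_o <- par[1]; chi <- par[2]; d_oh <- par[3]
    o <- c(0, 0, -d_o)
    u <- c(sin(chi), 0, -cos(chi))        # C2 axis, away from Mn
    v <- c(cos(chi), 0, sin(chi))
    half <- 104.5 / 2 * pi / 180
    h1 <- o + d_oh * (cos(half) * u + sin(half) * v)
    h2 <- o + d_oh * (cos(half) * u - sin(half) * v)
    list(o = o, h1 = h1, h2 = h2)
  }
  obj <- function(par) {
    w <- water_h(par)
    (sqrt(sum(w$h1^2)) - 2.62)^2 + (sqrt(sum(w$h2^2)) - 2.91)^2
  }
  opt <- stats::optim(c(2.22, 15 * pi / 180, 0.97), obj, method = "L-BFGS-B",
                      lower = c(2.12, 0, 0.95),
                      upper = c(2.32, pi / 3, 0.99))
  wat <- water_h(opt$par)

  ez <- c(0, 0, 1); ex <- c(1, 0, 0)
  rings <- list()
  ## axial His26: ring plane reference is the x-axis, dihedral 180 deg
  rings$His26 <- .imidazole_ring(ez, .rotate_about(ex, ez, pi), d_mn_nax)
  ## equatorial histidines at 120 and 240 deg in the xy-plane; dihedral is
  ## measured from the axial (z) direction about the Mn-N bond
  for (nm in c("His81", "His171")) {
    ang <- if (nm == "His81") 2 * pi / 3 else 4 * pi / 3
    u <- c(cos(ang), sin(ang), 0)
    dih <- if (nm == "His171") dihedral_deg * pi / 180 else 0
    w <- .rotate_about(ez, u, dih)
    rings[[nm]] <- .imidazole_ring(u, w, d_mn_neq)
  }

  coords <- rbind(
    Mn = c(0, 0, 0),
    O_w = wat$o, H_wp = wat$h1, H_w = wat$h2,
    N_e_His26 = rings$His26$n_e, H2_His26 = rings$His26$h2,
    H5_His26 = rings$His26$h5,
    N_e_His81 = rings$His81$n_e, H2_His81 = rings$His81$h2,
    H5_His81 = rings$His81$h5,
    N_e_His171 = rings$His171$n_e, H2_His171 = rings$His171$h2,
    H5_His171 = rings$His171$h5,
    O_d2_Asp167 = d_mn_od * ex)
  colnames(coords) <- c("x", "y", "z")
  if (jitter_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    jit <- matrix(stats::rnorm(3 * (nrow(coords) - 1), 0, jitter_sd),
                  ncol = 3)
    coords[-1, ] <- coords[-1, ] + jit
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  dmat <- as.matrix(stats::dist(coords))
  if (any(dmat[upper.tri(dmat)] < 0.9)) {
    stop("degenerate geometry: interatomic distance below 0.9 A",
         call. = FALSE)
  }
  structure(list(coords = coords, variant = variant,
                 ring_dihedral_his171_deg = dihedral_deg,
                 rng_seed = as.integer(seed)),
            class = "toy_site")
}

#' @export
print.toy_site <- function(x, ...) {
  r <- sqrt(rowSums(x$coords^2))
  cat(sprintf("<toy_site> %s (His171 ring dihedral %+g deg, seed %d)\n",
              x$variant, x$ring_dihedral_his171_deg, x$rng_seed))
  cat("  Mn distances (A): ",
      paste(sprintf("%s %.2f", names(r)[-1], r[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' Hyperfine tensor set from a toy site
#'
#' Protons get axial point-dipole tensors (unique axis along Mn-H, T from
#' the r^-3 law) with isotropic parts from `aiso_map`. Nitrogen tensors are
#' parametric, not ab initio: the dipolar part is the point-dipole value
#' along the Mn-N bond and the isotropic part of the axial His26 nitrogen is
#' chosen so its effective coupling along the molecular z-axis is 4 MHz (the
#' largest 14N coupling at the low-field edge); a placeholder quadrupole
#' tensor (|P_zz| = 0.8 MHz, axis along the bond) is attached to every 14N
#' and is labelled synthetic.
#'
#' @param site [build_toy_site()] result.
#' @param aiso_map Named list/vector of isotropic couplings (MHz) by atom
#'   name; defaults: `H_w` -0.45, `H_wp` 0, ring protons 0.
#' @param n26_aeff_z_mhz Target effective coupling of the His26 nitrogen
#'   along z, MHz (default 4).
#' @param n_eq_aiso_mhz Isotropic coupling of the equatorial nitrogens,
#'   MHz (default 2.5).
#' @return [tensor_set()] with source `"synthetic"`.
#' @export
tensors_from_site <- function(site, aiso_map = NULL, n26_aeff_z_mhz = 4,
                              n_eq_aiso_mhz = 2.5) {
  stopifnot(inherits(site, "toy_site"))
  defaults <- c(H_w = -0.45, H_wp = 0, H2_His26 = 0, H5_His26 = 0,
                H2_His81 = 0, H5_His81 = 0, H2_His171 = 0, H5_His171 = 0)
  if (!is.null(aiso_map)) {
    aiso_map <- unlist(aiso_map)
    defaults[names(aiso_map)] <- aiso_map
  }
  co <- site$coords
  need <- c(names(defaults), "N_e_His26", "N_e_His81", "N_e_His171")
  miss <- setdiff(need, rownames(co))
  if (length(miss)) stop("site is missing atoms: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  frame_along <- function(v) {
    u <- v / sqrt(sum(v^2))
    euler_angles(atan2(u[2], u[1]), acos(max(-1, min(1, u[3]))), 0)
  }
  tensors <- list()
  for (nm in names(defaults)) {
    v <- co[nm, ]
    r <- sqrt(sum(v^2))
    t <- point_dipole_T(r, "1H")
    tensors[[nm]] <- hyperfine_tensor("1H", defaults[[nm]],
                                      t_to_principal(t),
                                      frame = frame_along(v), id = nm)
  }
  quad0 <- function(fr) quadrupole_tensor(c(-0.4, -0.4, 0.8), frame = fr)
  for (nm in c("N_e_His26", "N_e_His81", "N_e_His171")) {
    v <- co[nm, ]
    r <- sqrt(sum(v^2))
    t <- point_dipole_T(r, "14N")
    fr <- frame_along(v)
    u <- v / r
    proj_z <- t * (3 * u[3]^2 - 1)  # dipolar projection along molecular z
    aiso <- if (nm == "N_e_His26") n26_aeff_z_mhz - proj_z else n_eq_aiso_mhz
    tensors[[nm]] <- hyperfine_tensor("14N", aiso, t_to_principal(t),
                                      frame = fr, id = nm, quad = quad0(fr))
  }
  tensor_set(tensors, source = "synthetic")
}

#' Add seeded white Gaussian noise to a spectrum
#'
#' @param spec [spectrum_1d()].
#' @param snr Signal-to-noise ratio: noise sd = max(amplitude) / snr.
#' @param seed Integer seed (reproducible; the global RNG state is
#'   restored afterwards).
#' @return Noisy [spectrum_1d()].
#' @export
add_noise <- function(spec, snr, seed = 1L) {
  stopifnot(inherits(spec, "spectrum_1d"), snr > 0)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  sigma <- max(abs(spec$amplitude)) / snr
  noisy <- spec$amplitude + stats::rnorm(length(spec$amplitude), 0, sigma)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  spectrum_1d(spec$axis, noisy, kind = spec$kind,
              meta = c(spec$meta, list(snr = snr, noise_seed = seed)))
}
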