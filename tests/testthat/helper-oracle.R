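# Exact-diagonalization oracle for the S = 5/2 spin Hamiltonian
#   H = g beta B S_z + D [S_z'^2 - S(S+1)/3] + E [S_x'^2 - S_y'^2]
# with the primed (zero-field) axes tilted by (theta, phi) relative to the
# field. Used only to validate the first-order closed forms; kept fully
# independent of the package implementation (explicit spin matrices,
# numerical eigenvalues).

spin_matrices_5half <- function() {
  s <- 5 / 2
  m <- seq(s, -s)  # descending, standard |s, m> ordering
  n <- length(m)
  sp <- matrix(0, n, n)  # raising operator S+
  for (i in 2:n) {
    mm <- m[i]
    sp[i - 1, i] <- sqrt(s * (s + 1) - mm * (mm + 1))
  }
  sm <- t(sp)
  list(sx = (sp + sm) / 2,
       sy = (sp - sm) / (2i),
       sz = diag(m))
}

# transition frequency (GHz) between adjacent levels dominated by
# ms and ms+1, at field b_mt along the lab z-axis, zero-field frame tilted
# by (theta, phi)
exact_transition_freq <- function(b_mt, d_ghz, e_ghz, theta, phi, ms, g) {
  sm <- spin_matrices_5half()
  # choose the zero-field axes (in the lab frame) so that the field (lab z)
  # has coordinates (sin th cos ph, sin th sin ph, cos th) in the zero-field
  # frame: R = (Rz(phi) Ry(theta))^T has exactly that third row
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0,
                             sin(b), 0, cos(b)), 3, 3)
  r <- t(rz(phi) %*% ry(theta))
  ux <- r[, 1]; uy <- r[, 2]; uz <- r[, 3]
  sop <- function(u) u[1] * sm$sx + u[2] * sm$sy + u[3] * sm$sz
  szp <- sop(uz); sxp <- sop(ux); syp <- sop(uy)
  geff <- hfepr::electron_ghz_per_mt(g)
  h <- geff * b_mt * sm$sz +
    d_ghz * (szp %*% szp - (35 / 12) * diag(6)) +
    e_ghz * (sxp %*% sxp - syp %*% syp)
  ev <- sort(Re(eigen((h + Conj(t(h))) / 2, only.values = TRUE)$values))
  # ascending eigenvalues correspond to ms = -5/2 ... +5/2 in the
  # Zeeman-dominated regime
  idx <- which(abs(ms - seq(-5 / 2, 5 / 2)) < 1e-9)
  ev[idx + 1] - ev[idx]
}
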