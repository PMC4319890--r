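# Shared fixtures built in code: small hand-laid molecules with known
# typing, plus geometry helpers for invariance checks.

# benzene: planar hexagon, alternating bond orders, implicit H = 1 per C
benzene_mol <- function() {
  theta <- (0:5) * pi / 3
  coords <- cbind(1.39 * cos(theta), 1.39 * sin(theta), 0)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = rep(c(2L, 1L), 3))
  m <- molecule3d("benzene", rep("C", 6), coords, bonds)
  m$atoms$hcount <- .ufsrat_implicit_h(m)
  m
}

# phenol: benzene plus a hydroxyl O on atom 1
phenol_mol <- function() {
  b <- benzene_mol()
  coords <- rbind(atom_coords(b), c(2.75, 0, 0))
  bonds <- rbind(b$bonds, data.frame(i = 1L, j = 7L, order = 1L))
  m <- molecule3d("phenol", c(rep("C", 6), "O"), coords, bonds)
  m$atoms$hcount <- .ufsrat_implicit_h(m)
  m
}

# implicit hydrogen counts via the package's valence model, applied to an
# already-built molecule
.ufsrat_implicit_h <- function(m) {
  bs <- numeric(n_atoms(m))
  for (k in seq_len(nrow(m$bonds))) {
    bs[m$bonds$i[k]] <- bs[m$bonds$i[k]] + m$bonds$order[k]
    bs[m$bonds$j[k]] <- bs[m$bonds$j[k]] + m$bonds$order[k]
  }
  val <- c(C = 4, N = 3, O = 2, S = 2, F = 1)[m$atoms$element]
  val[is.na(val)] <- 0
  as.integer(pmax(0, val - bs))
}

# water with explicit hydrogens
water_mol <- function() {
  molecule3d("water", c("O", "H", "H"),
             rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
             data.frame(i = c(1L, 1L), j = c(2L, 3L), order = 1L))
}

# uniform random rotation (QR with positive diagonal, det forced to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_transform <- function(mol, R, t) {
  xyz <- atom_coords(mol) %*% t(R)
  mol$atoms$x <- xyz[, 1] + t[1]
  mol$atoms$y <- xyz[, 2] + t[2]
  mol$atoms$z <- xyz[, 3] + t[3]
  mol
}

# descriptor shorthand used throughout the tests
desc48 <- function(mol, config = descriptor_config()) {
  m <- strip_hydrogens(mol)
  ufsrat_descriptors(m, assign_types(m), config)
}

# independent moment oracle via raw power sums (a different algebraic
# route than the central-moment implementation); the data are shifted by
# their first element before summing — central moments are shift-invariant
# and the shift keeps the power-sum cancellation well conditioned
oracle_moments <- function(d) {
  n <- length(d)
  s <- d - d[1]
  e1 <- sum(s) / n
  e2 <- sum(s^2) / n
  e3 <- sum(s^3) / n
  v <- e2 - e1^2
  mu3 <- e3 - 3 * e1 * e2 + 2 * e1^3
  c(e1 + d[1], v, if (v < 1e-12) 0 else mu3 / v^1.5)
}
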