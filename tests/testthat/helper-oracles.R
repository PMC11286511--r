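# Independent oracles and shared fixtures for the test suite.

# Quaternion (Horn) superposition: rotation-free RMSD of mobile onto target
# via the largest eigenvalue of the 4x4 quaternion matrix. Independent of
# the SVD/Kabsch code path under test.
quaternion_rmsd <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  S <- crossprod(A, B)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# Quaternion-method rotation angle (degrees) between paired point sets,
# used as an independent check on fitted twists.
quaternion_angle <- function(mobile, target) {
  A <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  B <- sweep(as.matrix(target), 2, colMeans(target))
  S <- crossprod(A, B)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, which.max(ev$values)]
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

# Random proper rotation matrix (via QR of a Gaussian matrix).
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# A long ideal helix split into protomers with bridging fragments whose
# termini coincide exactly with the junction residues: an exact loop-closure
# fixture.
split_helix_fixture <- function(n_res = 30, cuts = list(1:9, 12:20, 23:30),
                                bridges = list(9:12, 20:23)) {
  bb <- helifil:::build_backbone(n_res, helifil:::HELIX_PHI,
                                 helifil:::HELIX_PSI, cb = FALSE)
  at <- helifil:::backbone_atoms(bb)
  protomers <- lapply(cuts, function(rr)
    structure3d(at[at$resno %in% rr, , drop = FALSE]))
  frags <- lapply(seq_along(bridges), function(i)
    helifil:::make_fragment(sprintf("bridge_%d", i),
                            lapply(bb, function(m)
                              m[bridges[[i]], , drop = FALSE])))
  list(protomers = protomers, db = helifil:::new_fragment_db(frags),
       full = structure3d(at))
}

# Regular planar dot grids with opposing normals, for the Sc closed form.
plane_dots <- function(gap, spacing = 0.3, extent = 10) {
  g <- expand.grid(x = seq(0, extent, by = spacing),
                   y = seq(0, extent, by = spacing))
  n <- nrow(g)
  list(a = cbind(g$x, g$y, 0),
       na = matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE),
       b = cbind(g$x, g$y, gap),
       nb = matrix(rep(c(0, 0, -1), n), ncol = 3, byrow = TRUE))
}

# Two-chain structure from one subunit and an x offset (interface fixtures).
offset_pair <- function(subunit, dx) {
  a <- subunit$atoms; a$chain <- "A"
  b <- subunit$atoms; b$chain <- "B"; b$x <- b$x + dx
  structure3d(rbind(a, b))
}
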