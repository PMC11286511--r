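# Internal backbone construction from internal coordinates (NeRF).
# Ideal poly-alanine geometry: bond lengths/angles from standard values,
# alpha-helix torsions phi=-57, psi=-47, omega=180, giving ~1.5 A rise and
# ~100 deg rotation per residue (CA-CA ~3.8 A).

BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231, CA_CB = 1.530)
ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7,
           CA_C_O = 120.5, N_CA_CB = 110.5)
HELIX_PHI <- -57
HELIX_PSI <- -47

# Place atom D given A-B-C with bond |CD|, angle B-C-D, dihedral A-B-C-D.
nerf_place <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- deg2rad(angle_deg); dih <- deg2rad(dihedral_deg)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

# Build an n_res poly-alanine backbone (N, CA, C, O, CB) from torsion lists.
# phi[1] and psi[n] still shape O/CB placement; omega fixed at 180.
build_backbone <- function(n_res, phi, psi, cb = TRUE) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  N <- matrix(0, n_res, 3); CA <- matrix(0, n_res, 3)
  C <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND["N_CA"], 0, 0)
  C[1, ] <- nerf_place(c(-1, 1, 0), N[1, ], CA[1, ], BOND["CA_C"],
                       ANGLE["N_CA_C"], phi[1])
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], BOND["C_N"],
                             ANGLE["CA_C_N"], psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], BOND["N_CA"],
                              ANGLE["C_N_CA"], 180)      # omega
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], BOND["CA_C"],
                             ANGLE["N_CA_C"], phi[i + 1])
  }
  O <- matrix(0, n_res, 3)
  for (i in seq_len(n_res))
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], BOND["C_O"],
                         ANGLE["CA_C_O"], psi[i] + 180)
  out <- list(N = N, CA = CA, C = C, O = O)
  if (cb) {
    CB <- matrix(0, n_res, 3)
    for (i in seq_len(n_res))
      CB[i, ] <- nerf_place(C[i, ], N[i, ], CA[i, ], BOND["CA_CB"],
                            ANGLE["N_CA_CB"], 123)       # L-chirality improper
    out$CB <- CB
  }
  out
}

# Flatten a build_backbone() result into an atom table.
backbone_atoms <- function(bb, resno_start = 1L, chain = "A", resid = "ALA") {
  n <- nrow(bb$N)
  order_names <- intersect(c("N", "CA", "C", "O", "CB"), names(bb))
  rows <- lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(order_names, function(nm) {
      data.frame(name = nm,
                 element = substr(nm, 1, 1),
                 x = bb[[nm]][i, 1], y = bb[[nm]][i, 2], z = bb[[nm]][i, 3],
                 resno = resno_start + i - 1L, resid = resid, chain = chain,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# Rotation matrix mapping unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    w <- orthobasis(u)[, 1]
    return(rot_axis(w, 180))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  rot_axis(ax, rad2deg(atan2(sqrt(sum(ax^2)), d)))
}

# Align a helix atom table so its helical axis runs along +z (N->C up),
# passes through x = y = 0, and the CA centroid sits at z = 0. The axis is
# recovered exactly from the per-residue screw transform (Kabsch between
# residues 1..n-1 and 2..n), not from the coordinate covariance, which is
# biased for short helices.
align_helix_z <- function(atoms) {
  nres <- max(atoms$resno)
  ord <- order(atoms$resno, match(atoms$name, c("N", "CA", "C", "O", "CB")))
  at <- atoms[ord, ]
  m1 <- as.matrix(at[at$resno <= nres - 1, c("x", "y", "z")])
  m2 <- as.matrix(at[at$resno >= 2, c("x", "y", "z")])
  k <- kabsch(m1, m2)
  p <- screw_decompose(rigid_transform(k$rotation, k$translation))
  ax <- p$axis_direction
  ca <- as.matrix(atoms[atoms$name == "CA", c("x", "y", "z")])
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) {
    # rise-positive convention already orients the axis; guard anyway
    ax <- -ax
  }
  R <- rotation_between(ax, c(0, 0, 1))
  xyz <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, p$axis_point) %*% t(R)
  xyz[, 3] <- xyz[, 3] - mean(xyz[atoms$name == "CA", 3])
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}
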