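#' Propagate a subunit into a helical filament
#'
#' Applies the generating transform `t` repeatedly to `subunit`: copy k
#' (k = 0..n-1) carries coordinates `t^k` applied to the subunit, under a
#' distinct chain id (A, B, ..., Z, then AA, AB, ... which require mmCIF for
#' file output). Copy 0 is the input subunit itself.
#'
#' @param subunit a [structure3d] (its own chain ids are collapsed).
#' @param t a [rigid_transform] (or a preset list from [get_preset]).
#' @param n number of copies (>= 1).
#' @return object of class `"filament"`: list with `subunit`, `transform`,
#'   `n_subunits`, and `structure` (the combined [structure3d]).
#' @export
propagate <- function(subunit, t, n) {
  if (!is.null(t$transform)) t <- t$transform
  if (n < 1) stopf("n must be >= 1")
  if (length(chain_ids(subunit)) > 1) {
    # collapse multi-chain subunits: renumber residues consecutively
    at <- subunit$atoms
    key <- paste(at$chain, at$resno)
    at$resno <- as.integer(factor(key, levels = unique(key)))
    at$chain <- "A"
    subunit <- structure3d(at, subunit$metadata)
  }
  ids <- chain_id_seq(n)
  xyz0 <- coords(subunit)
  parts <- vector("list", n)
  cur <- rigid_transform(diag(3), c(0, 0, 0))
  for (k in seq_len(n)) {
    at <- subunit$atoms
    at[, c("x", "y", "z")] <- apply_transform(cur, xyz0)
    at$chain <- ids[k]
    parts[[k]] <- at
    cur <- compose_transform(t, cur)
  }
  structure(list(subunit = subunit, transform = t, n_subunits = as.integer(n),
                 structure = structure3d(do.call(rbind, parts))),
            class = "filament")
}

chain_id_seq <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, two)[seq_len(n)]
}

#' @export
print.filament <- function(x, ...) {
  p <- screw_decompose(x$transform)
  cat(sprintf("filament: %d subunits x %d atoms; rise %.3f A, twist %.2f deg\n",
              x$n_subunits, n_atoms(x$subunit), p$rise, p$twist))
  invisible(x)
}

# Per-subunit coordinate matrices from a filament, a multi-chain structure3d
# (chains in order of appearance), or a list of matrices.
subunit_coord_list <- function(x) {
  if (inherits(x, "filament")) x <- x$structure
  if (inherits(x, "structure3d")) {
    ids <- chain_ids(x)
    return(lapply(ids, function(ch)
      as.matrix(x$atoms[x$atoms$chain == ch, c("x", "y", "z")])))
  }
  if (is.list(x)) return(lapply(x, as.matrix))
  stopf("expected a filament, structure3d, or list of coordinate matrices")
}

# Heavy-atom-only variant (element H dropped) keeping subunit partition.
subunit_heavy_list <- function(x) {
  if (inherits(x, "filament")) x <- x$structure
  if (inherits(x, "structure3d")) {
    ids <- chain_ids(x)
    at <- x$atoms[toupper(x$atoms$element) != "H", , drop = FALSE]
    return(lapply(ids, function(ch)
      as.matrix(at[at$chain == ch, c("x", "y", "z")])))
  }
  subunit_coord_list(x)
}

#' Fit helical parameters from filament coordinates
#'
#' Estimates the generating screw transform of a filament from coordinates
#' alone: the least-squares (Kabsch) rigid transform is computed for every
#' consecutive subunit pair, the transforms are averaged (rotations via
#' projection of the mean matrix back onto SO(3)), and the average is screw-
#' decomposed into rise and twist. On noise-free generated filaments this
#' recovers the generating parameters to better than 1e-6.
#'
#' @param x a `filament`, a multi-chain [structure3d] whose chains are
#'   consecutive subunits in order of appearance, or a list of >= 3
#'   coordinate matrices with identical atom ordering.
#' @return a `helical_params` object (see [screw_decompose]).
#' @export
fit_helical_params <- function(x) {
  subs <- subunit_coord_list(x)
  if (length(subs) < 2) stopf("need >= 2 consecutive subunits to fit")
  nat <- vapply(subs, nrow, integer(1))
  if (length(unique(nat)) != 1)
    stopf("subunits have mismatched atom counts: %s", paste(nat, collapse = ", "))
  Rsum <- matrix(0, 3, 3); tsum <- c(0, 0, 0)
  npair <- length(subs) - 1
  for (i in seq_len(npair)) {
    k <- kabsch(subs[[i]], subs[[i + 1]])
    Rsum <- Rsum + k$rotation
    tsum <- tsum + k$translation
  }
  sv <- svd(Rsum / npair)
  d <- sign(det(sv$u %*% t(sv$v)))
  Rbar <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  screw_decompose(rigid_transform(Rbar, tsum / npair))
}

#' Ring count of a helical symmetry
#'
#' Smallest number of subunit steps n (2..`n_max`) whose cumulative twist
#' closes onto a full number of turns within `angle_tol`: the number of
#' subunits seen as a ring in filament cross-section. Returns `NA` when no n
#' qualifies, and for zero twist (no ring is defined).
#'
#' The default 30 degree tolerance admits residuals like 24.5 degrees at
#' n = 5 for a twist of -148.9 degrees while rejecting the 62.2 degree
#' residual at n = 2. Invariant to twist sign and to adding whole turns.
#'
#' @param p a `helical_params` object (or bare twist in degrees).
#' @param angle_tol closure tolerance, degrees.
#' @param n_max largest ring size scanned.
#' @return integer ring count, or `NA_integer_`.
#' @export
ring_count <- function(p, angle_tol = 30, n_max = 24) {
  twist <- if (inherits(p, "helical_params")) p$twist else as.numeric(p)
  if (abs(wrap_angle(twist)) < 1e-12) return(NA_integer_)
  for (n in 2:n_max) {
    resid <- abs(n * twist - 360 * round(n * twist / 360))
    if (resid < angle_tol) return(as.integer(n))
  }
  NA_integer_
}

#' Strand step of a filament
#'
#' Smallest index offset k >= 1 at which subunit copies i and i+k share at
#' least one heavy-atom pair within `contact_cutoff`, computed from a central
#' subunit. A filament whose contacting subunits are k steps apart is a
#' k-start (k parallel strands) when k > 1.
#'
#' @param f a `filament` (or multi-chain [structure3d]) with >= 4 subunits.
#' @param contact_cutoff heavy-atom contact distance, Angstrom.
#' @return integer offset k.
#' @export
strand_step <- function(f, contact_cutoff = 4.5) {
  subs <- subunit_heavy_list(f)
  if (length(subs) < 4) stopf("need >= 4 subunits")
  i <- ceiling(length(subs) / 2)
  for (k in seq_len(length(subs) - i)) {
    if (min_dist(subs[[i]], subs[[i + k]]) <= contact_cutoff)
      return(as.integer(k))
  }
  stopf("no inter-subunit contacts at any offset (cutoff %.2f A)", contact_cutoff)
}

#' Detect antiparallel (dihedral) subunit arrangement
#'
#' Computes each subunit's principal axis (leading eigenvector of its CA
#' coordinate covariance, direction disambiguated N-terminus to C-terminus)
#' and its orientation sign along the filament axis. An arrangement is
#' antiparallel -- as in a D1 dihedral filament, where a two-fold axis
#' perpendicular to the helical axis flips alternate strands -- when both
#' signs occur.
#'
#' @param s a `filament` or multi-chain [structure3d]; one subunit per chain.
#' @param axis filament axis unit vector (default +z).
#' @return list with `antiparallel` (logical) and `signs` (named +1/-1 per
#'   chain).
#' @export
detect_antiparallel <- function(s, axis = c(0, 0, 1)) {
  if (inherits(s, "filament")) s <- s$structure
  axis <- axis / sqrt(sum(axis^2))
  ids <- chain_ids(s)
  signs <- vapply(ids, function(ch) {
    at <- s$atoms[s$atoms$chain == ch & s$atoms$name == "CA", , drop = FALSE]
    ca <- as.matrix(at[, c("x", "y", "z")])
    if (nrow(ca) < 2) stopf("chain %s: too few CA atoms for a principal axis", ch)
    cc <- sweep(ca, 2, colMeans(ca))
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    if (ev$values[1] < 1e-9 ||
        (ev$values[1] - ev$values[2]) / ev$values[1] < 1e-6)
      stopf("chain %s: degenerate (near-spherical) subunit, principal axis undefined", ch)
    v <- ev$vectors[, 1]
    if (sum((ca[nrow(ca), ] - ca[1, ]) * v) < 0) v <- -v   # N -> C
    s1 <- sum(v * axis)
    if (s1 >= 0) 1 else -1
  }, numeric(1))
  names(signs) <- ids
  list(antiparallel = length(unique(signs)) > 1, signs = signs)
}

#' Sample candidate helical docks on a parameter grid
#'
#' Places the subunit at a radial offset from the +z filament axis (with an
#' axial spin about its own centroid), generates the first five copies under
#' a screw of the given rise and twist, and records clash and contact
#' statistics for each grid point. A sample is flagged as a clash when any
#' inter-copy heavy-atom pair is closer than `clash_cutoff`; `n_contacts`
#' counts heavy-atom pairs between copy 1 and the later copies within
#' `contact_cutoff`. Grid order is deterministic (`expand.grid` over rise,
#' twist, radial, spin; rise varying fastest).
#'
#' @param subunit a [structure3d].
#' @param grid named list with numeric vectors `rise` (Angstrom), `twist`
#'   (degrees), and optionally `radial` (Angstrom, default 0) and `spin`
#'   (degrees, default 0).
#' @param clash_cutoff,contact_cutoff heavy-atom distance cutoffs, Angstrom.
#' @param n_copies copies propagated per sample.
#' @return data.frame with one row per grid point: rise, twist, radial, spin,
#'   `min_distance`, `n_contacts`, `clash`.
#' @export
sample_docks <- function(subunit, grid, clash_cutoff = 2.4,
                         contact_cutoff = 4.5, n_copies = 5) {
  if (is.null(grid$rise) || is.null(grid$twist) ||
      !length(grid$rise) || !length(grid$twist))
    stopf("grid must supply non-empty rise and twist vectors")
  g <- expand.grid(rise = grid$rise, twist = grid$twist,
                   radial = grid$radial %||% 0, spin = grid$spin %||% 0,
                   KEEP.OUT.ATTRS = FALSE)
  xyz0 <- coords(heavy(subunit))
  cen <- colMeans(xyz0)
  out <- g
  out$min_distance <- NA_real_
  out$n_contacts <- NA_integer_
  for (r in seq_len(nrow(g))) {
    placed <- sweep(sweep(xyz0, 2, cen) %*% t(rot_z(g$spin[r])), 2,
                    c(cen[1] + g$radial[r], cen[2], cen[3]), "+")
    t <- rigid_transform(rot_z(g$twist[r]), c(0, 0, g$rise[r]))
    copies <- vector("list", n_copies)
    cur <- rigid_transform(diag(3), c(0, 0, 0))
    for (k in seq_len(n_copies)) {
      copies[[k]] <- apply_transform(cur, placed)
      cur <- compose_transform(t, cur)
    }
    mind <- Inf; ncon <- 0L
    for (a in seq_len(n_copies - 1)) for (b in seq(a + 1, n_copies)) {
      d2 <- cross_dist2(copies[[a]], copies[[b]])
      mind <- min(mind, sqrt(min(d2)))
      if (a == 1) ncon <- ncon + sum(d2 <= contact_cutoff^2)
    }
    out$min_distance[r] <- mind
    out$n_contacts[r] <- ncon
  }
  out$clash <- out$min_distance < clash_cutoff
  out
}
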