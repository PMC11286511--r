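# Kabsch least-squares rigid superposition: returns the transform mapping
# `mobile` onto `target` (y ~ R x + t) and the residual RMSD. The SVD-based
# solution is the global minimum over rigid transforms.
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ct - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(rotation = R, translation = trans, rmsd = rmsd)
}

#' Optimal rigid superposition of two point sets
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `target` over all
#' proper rigid transforms; the returned RMSD is the global minimum. Point
#' correspondences are row-wise.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3, in correspondence.
#' @return list with `transform` (a [rigid_transform] mapping mobile onto
#'   target) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stopf("point counts differ (%d vs %d)", nrow(mobile), nrow(target))
  if (nrow(mobile) < 3) stopf("need >= 3 points to superpose")
  for (m in list(mobile, target)) {
    cc <- sweep(m, 2, colMeans(m))
    ev <- eigen(crossprod(cc), symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] < 1e-12 * max(ev[1], 1))
      stopf("degenerate (collinear) point set: superposition not unique")
  }
  k <- kabsch(mobile, target)
  list(transform = rigid_transform(k$rotation, k$translation), rmsd = k$rmsd)
}

# Backbone coordinates (N, CA, C, O) of the n_res terminal residues of a
# single-chain structure; end = "N" (first residues) or "C" (last).
#' @rdname find_loop_candidates
#' @param s single-chain [structure3d].
#' @param end `"N"` or `"C"` terminus.
#' @export
terminal_backbone <- function(s, end = c("N", "C"), n_res = 1) {
  end <- match.arg(end)
  at <- s$atoms
  resnos <- unique(at$resno)
  pick <- if (end == "N") utils::head(resnos, n_res) else utils::tail(resnos, n_res)
  rows <- do.call(rbind, lapply(pick, function(r) {
    res <- at[at$resno == r & at$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
    res[match(c("N", "CA", "C", "O"), res$name), , drop = FALSE]
  }))
  if (any(is.na(rows$name)))
    stopf("terminal residue(s) missing backbone atoms (need N, CA, C, O)")
  as.matrix(rows[, c("x", "y", "z")])
}

fragment_res_backbone <- function(frag, resnos) {
  cf <- frag$coords
  do.call(rbind, lapply(resnos, function(r) {
    res <- cf[cf$resno == r, , drop = FALSE]
    as.matrix(res[match(c("N", "CA", "C", "O"), res$atom), c("x", "y", "z")])
  }))
}

#' Find loop candidates bridging two termini
#'
#' Searches a fragment database for backbone fragments whose terminal
#' residues superpose jointly onto the two target termini -- the C-terminal
#' residue(s) of the upstream chain and the N-terminal residue(s) of the
#' downstream chain -- within an RMSD tolerance. The default tolerance of
#' 0.35 Angstrom is the alignment acceptance used during filament loop
#' design. Candidates are ranked purely by RMSD (ascending, ties broken by
#' fragment id); an empty list (no error) is returned when nothing passes.
#'
#' "Terminal residues" means the backbone N, CA, C, O of `n_term_res`
#' residues per side (default 1, i.e. 4+4 atoms jointly superposed).
#'
#' @param n_side backbone coordinate matrix of the upstream (chain A
#'   C-terminal) residues, as from [terminal_backbone].
#' @param c_side backbone coordinate matrix of the downstream (chain B
#'   N-terminal) residues.
#' @param db a `fragment_db`.
#' @param tolerance RMSD acceptance, Angstrom.
#' @param n_term_res residues per side used for the alignment (1-3).
#' @return list of candidates: `fragment_id`, `rmsd`, `aligned_coords`
#'   (full fragment backbone after superposition, data.frame).
#' @export
find_loop_candidates <- function(n_side, c_side, db, tolerance = 0.35,
                                 n_term_res = 1) {
  if (!inherits(db, "fragment_db")) stopf("db must be a fragment_db")
  if (!length(db$fragments)) stopf("fragment database is empty")
  if (n_term_res < 1 || n_term_res > 3) stopf("n_term_res must be 1-3")
  target <- rbind(as.matrix(n_side), as.matrix(c_side))
  if (nrow(target) != 8 * n_term_res)
    stopf("termini must each supply N, CA, C, O for %d residue(s)", n_term_res)
  cands <- list()
  for (f in db$fragments) {
    if (f$length < 2 * n_term_res + 1) next   # need at least one interior residue
    mob <- rbind(fragment_res_backbone(f, seq_len(n_term_res)),
                 fragment_res_backbone(f, f$length - n_term_res + seq_len(n_term_res)))
    sp <- superpose(mob, target)
    if (sp$rmsd <= tolerance) {
      cf <- f$coords
      cf[, c("x", "y", "z")] <-
        apply_transform(sp$transform, as.matrix(cf[, c("x", "y", "z")]))
      cands[[length(cands) + 1L]] <- list(fragment_id = f$id, rmsd = sp$rmsd,
                                          length = f$length,
                                          aligned_coords = cf)
    }
  }
  if (!length(cands)) return(list())
  ord <- order(vapply(cands, `[[`, numeric(1), "rmsd"),
               vapply(cands, `[[`, character(1), "fragment_id"))
  cands[ord]
}

#' Close protomers into a single chain with loop fragments
#'
#' Stitches an ordered list of protomer structures into one chain, inserting
#' the interior residues of each aligned loop candidate between consecutive
#' protomers. Each loop's terminal residues must already sit on the junction
#' termini (within `endpoint_tol` mean backbone deviation, default 0.5
#' Angstrom); the stitched chain is renumbered consecutively and every
#' junction's peptide C-N bond must fall in [1.2, 1.5] Angstrom, otherwise a
#' stitching error names the junction. Stitched loops keep poly-alanine
#' identity: loop sequence design is out of scope.
#'
#' @param protomers list of single-chain [structure3d] objects, N-to-C order.
#' @param loops list of loop candidates (from [find_loop_candidates]),
#'   one per junction: `length(loops) == length(protomers) - 1`.
#' @param endpoint_tol maximum mean deviation of a loop's terminal-residue
#'   backbone from the junction termini, Angstrom.
#' @return single-chain [structure3d], residues renumbered from 1.
#' @export
close_chain <- function(protomers, loops, endpoint_tol = 0.5) {
  if (length(loops) != length(protomers) - 1)
    stopf("need exactly one loop per junction (%d protomers -> %d loops)",
          length(protomers), length(protomers) - 1)
  pieces <- list()
  for (j in seq_along(protomers)) {
    at <- protomers[[j]]$atoms
    at$chain <- "A"
    pieces[[length(pieces) + 1L]] <- at
    if (j <= length(loops)) {
      lc <- loops[[j]]
      cf <- lc$aligned_coords
      L <- max(cf$resno)
      # endpoint check: loop terminal residues vs junction termini
      a_c <- terminal_backbone(protomers[[j]], "C")
      b_n <- terminal_backbone(protomers[[j + 1]], "N")
      ends <- rbind(
        as.matrix(cf[cf$resno == 1, c("x", "y", "z")][match(c("N", "CA", "C", "O"), cf$atom[cf$resno == 1]), ]),
        as.matrix(cf[cf$resno == L, c("x", "y", "z")][match(c("N", "CA", "C", "O"), cf$atom[cf$resno == L]), ]))
      dev <- mean(sqrt(rowSums((ends - rbind(a_c, b_n))^2)))
      if (dev > endpoint_tol)
        stopf("stitching error at junction %d: loop endpoints %.2f A from termini (max %.2f)",
              j, dev, endpoint_tol)
      interior <- cf[cf$resno > 1 & cf$resno < L, , drop = FALSE]
      if (nrow(interior)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          name = interior$atom, element = substr(interior$atom, 1, 1),
          x = interior$x, y = interior$y, z = interior$z,
          resno = interior$resno, resid = "ALA", chain = "A",
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, pieces)
  # renumber residues consecutively in encounter order (piece-aware so a
  # piece boundary never merges two residues sharing a number)
  piece_of <- rep(seq_along(pieces), vapply(pieces, nrow, integer(1)))
  key <- paste(piece_of, atoms$resno)
  atoms$resno <- as.integer(factor(key, levels = unique(key)))
  out <- structure3d(atoms)
  check_junction_geometry(out)
  out
}

# Peptide-bond check over the whole stitched chain: every consecutive
# residue pair's C-N distance must lie in [1.2, 1.5] A.
check_junction_geometry <- function(s) {
  at <- s$atoms
  resnos <- unique(at$resno)
  for (i in seq_len(length(resnos) - 1)) {
    cpos <- at[at$resno == resnos[i] & at$name == "C", c("x", "y", "z")]
    npos <- at[at$resno == resnos[i + 1] & at$name == "N", c("x", "y", "z")]
    if (!nrow(cpos) || !nrow(npos)) next
    d <- sqrt(sum((as.numeric(cpos[1, ]) - as.numeric(npos[1, ]))^2))
    if (d < 1.2 || d > 1.5)
      stopf("stitching error between residues %d and %d: C-N distance %.2f A outside [1.2, 1.5]",
            resnos[i], resnos[i + 1], d)
  }
  invisible(TRUE)
}
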