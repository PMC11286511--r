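#' @name interface_metrics
#' @title Interface metrics and the design filter pipeline
#' @description
#' Four metrics decide whether a docked filament design is worth keeping:
#' the buried interface area between neighbouring subunits, the
#' Lawrence-Colman shape complementarity (Sc) of the mated surfaces, the
#' number of interface residues left with buried-but-unsatisfied polar
#' atoms, and a bound-minus-unbound energy gap. The energy here is a
#' transparent pairwise contact pseudo-energy (its absolute scale is a
#' package convention, not an all-atom force field), and the filter
#' thresholds are configuration. All metrics are defined on heavy atoms.
NULL

# van der Waals radii (Angstrom) used for SASA and surface dots.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

vdw_radius <- function(element) {
  el <- toupper(element)
  r <- VDW_RADII[el]
  if (any(is.na(r)))
    stopf("no van der Waals radius for element(s): %s",
          paste(unique(el[is.na(r)]), collapse = ", "))
  unname(r)
}

# Deterministic golden-spiral quadrature points on the unit sphere.
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Canonical molecule frame: principal axes of the heavy-atom cloud with
# signs fixed by third central moments, right-handed. Quadrature points are
# generated in this frame so SASA is invariant under rigid motion of the
# molecule (for generic shapes; degenerate clouds fall back to the lab
# frame).
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  cc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[1] < 1e-9) return(diag(3))
  gaps <- diff(ev$values) / ev$values[1]
  if (any(abs(gaps) < 1e-9)) return(diag(3))
  V <- ev$vectors
  for (k in 1:2) {
    m3 <- mean((cc %*% V[, k])^3)
    if (abs(m3) > 1e-9 && m3 < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

# Core Shrake-Rupley on bare coordinates + radii.
sasa_xyz <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  if (n == 0) return(numeric(0))
  fr <- canonical_frame(xyz)
  pts0 <- golden_spiral(n_points) %*% t(fr)
  rs <- radii + probe
  areas <- numeric(n)
  d2full <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2full[i, ] < (rs[i] + radii + probe)^2)
    nb <- nb[nb != i]
    pts <- sweep(pts0 * rs[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & (dj2 > rs[j]^2)
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    areas[i] <- 4 * pi * rs[i]^2 * frac
  }
  areas
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom solvent-accessible surface areas from probe-inflated van der
#' Waals spheres sampled with a deterministic golden-spiral quadrature
#' (default 960 points per sphere, oriented in a canonical molecule frame so
#' the result is invariant under rigid motion). Hydrogen atoms are ignored;
#' radii: C 1.7, N 1.55, O 1.52, S 1.8 Angstrom.
#'
#' @param s a [structure3d].
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points quadrature points per sphere.
#' @return numeric vector of per-atom areas (Angstrom^2) for the heavy atoms
#'   of `s`, with the grand total in `attr(, "total")`.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960) {
  hs <- heavy(s)
  a <- sasa_xyz(coords(hs), vdw_radius(hs$atoms$element), probe, n_points)
  names(a) <- paste0(hs$atoms$chain, hs$atoms$resno, ".", hs$atoms$name)
  attr(a, "total") <- sum(a)
  a
}

# Resolve (filament or multi-chain structure, i, j) into two heavy-atom
# tables.
pair_subunits <- function(f, i, j) {
  if (inherits(f, "filament")) f <- f$structure
  ids <- chain_ids(f)
  if (i == j) stopf("need two distinct subunits")
  if (i < 1 || j < 1 || i > length(ids) || j > length(ids))
    stopf("subunit index out of range (1..%d)", length(ids))
  at <- f$atoms[toupper(f$atoms$element) != "H", , drop = FALSE]
  list(a = at[at$chain == ids[i], , drop = FALSE],
       b = at[at$chain == ids[j], , drop = FALSE])
}

#' Buried interface area between two subunits
#'
#' Total buried solvent-accessible area of the pair:
#' `sasa(i) + sasa(j) - sasa(i and j together)` -- the both-sides total, the
#' convention under which a 700 Angstrom^2 threshold matches common design
#' reporting. Set `per_side = TRUE` for the half value. Non-contacting pairs
#' return exactly 0.
#'
#' @param f a `filament` or multi-chain [structure3d].
#' @param i,j subunit (chain) indices, 1-based.
#' @param probe probe radius, Angstrom.
#' @param per_side report per-side (half) buried area instead of the total.
#' @param n_points quadrature points per sphere.
#' @return buried area, Angstrom^2.
#' @export
interface_area <- function(f, i, j, probe = 1.4, per_side = FALSE,
                           n_points = 960) {
  p <- pair_subunits(f, i, j)
  xa <- as.matrix(p$a[, c("x", "y", "z")])
  xb <- as.matrix(p$b[, c("x", "y", "z")])
  ra <- vdw_radius(p$a$element); rb <- vdw_radius(p$b$element)
  rmax <- max(ra, rb)
  if (min_dist(xa, xb) > 2 * (rmax + probe)) return(0)
  sa <- sum(sasa_xyz(xa, ra, probe, n_points))
  sb <- sum(sasa_xyz(xb, rb, probe, n_points))
  sab <- sum(sasa_xyz(rbind(xa, xb), c(ra, rb), probe, n_points))
  out <- max(0, sa + sb - sab)
  if (per_side) out / 2 else out
}

# Exposed van der Waals surface dots for one side: dot positions, outward
# radial normals, and owning-atom index. Dots inside any other atom of the
# same side are removed.
surface_dots <- function(xyz, radii, density = 10) {
  dots <- list(); normals <- list(); owner <- list()
  n <- nrow(xyz)
  d2full <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    npt <- max(8L, round(density * 4 * pi * radii[i]^2))
    u <- golden_spiral(npt)
    p <- sweep(u * radii[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, npt)
    nb <- which(d2full[i, ] < (radii[i] + radii)^2)
    nb <- nb[nb != i]
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      keep <- keep & (dj2 > radii[j]^2)
    }
    if (any(keep)) {
      dots[[length(dots) + 1L]] <- p[keep, , drop = FALSE]
      normals[[length(normals) + 1L]] <- u[keep, , drop = FALSE]
      owner[[length(owner) + 1L]] <- rep(i, sum(keep))
    }
  }
  list(dots = do.call(rbind, dots), normals = do.call(rbind, normals),
       owner = unlist(owner))
}

#' Shape complementarity from prepared dot surfaces
#'
#' Core of the Lawrence-Colman Sc statistic: for every dot of one patch the
#' nearest dot of the partner patch is found and scored
#' `exp(-w * d^2) * (n_a . -n_b)`; the statistic is the mean of the two
#' directional medians. Takes prepared interface patches (positions +
#' outward unit normals); [shape_complementarity] builds these from atomic
#' structures.
#'
#' @param dots_a,dots_b n x 3 dot positions of the two patches.
#' @param normals_a,normals_b matching outward unit normals.
#' @param w distance weight, 1/Angstrom^2.
#' @return Sc value in [-1, 1].
#' @export
sc_dots <- function(dots_a, normals_a, dots_b, normals_b, w = 0.5) {
  if (!nrow(dots_a) || !nrow(dots_b))
    stopf("undefined Sc: empty buried patch")
  score_side <- function(da, na, db, nb) {
    d2 <- cross_dist2(da, db)
    jn <- max.col(-d2, ties.method = "first")
    d2min <- d2[cbind(seq_len(nrow(da)), jn)]
    dotn <- rowSums(na * -nb[jn, , drop = FALSE])
    stats::median(exp(-w * d2min) * dotn)
  }
  (score_side(dots_a, normals_a, dots_b, normals_b) +
     score_side(dots_b, normals_b, dots_a, normals_a)) / 2
}

#' Shape complementarity of a subunit interface
#'
#' Builds exposed van der Waals dot surfaces for both subunits, keeps the
#' buried (interface) patch of each -- dots within `patch_cutoff` of the
#' partner's van der Waals surface -- trims a peripheral band of width
#' `band_trim` from the patch edge, and evaluates the Sc statistic via
#' [sc_dots]. Symmetric in i and j; bounded in [-1, 1]; 1 means perfectly
#' mated surfaces.
#'
#' @inheritParams interface_area
#' @param w Sc distance weight, 1/Angstrom^2.
#' @param band_trim peripheral band excluded from scoring, Angstrom.
#' @param density dot density, dots/Angstrom^2.
#' @param patch_cutoff distance from a dot to the partner's van der Waals
#'   surface below which the dot belongs to the interface patch, Angstrom.
#' @return Sc value.
#' @export
shape_complementarity <- function(f, i, j, w = 0.5, band_trim = 1.5,
                                  density = 10, patch_cutoff = 2.8) {
  p <- pair_subunits(f, i, j)
  xa <- as.matrix(p$a[, c("x", "y", "z")])
  xb <- as.matrix(p$b[, c("x", "y", "z")])
  ra <- vdw_radius(p$a$element); rb <- vdw_radius(p$b$element)
  sa <- surface_dots(xa, ra, density)
  sb <- surface_dots(xb, rb, density)
  patch <- function(sd, xyz_other, r_other) {
    d2 <- cross_dist2(sd$dots, xyz_other)
    surf_d <- sqrt(d2) - matrix(r_other, nrow(sd$dots), length(r_other),
                                byrow = TRUE)
    apply(surf_d, 1, min) < patch_cutoff
  }
  ina <- patch(sa, xb, rb)
  inb <- patch(sb, xa, ra)
  if (!any(ina) || !any(inb)) stopf("undefined Sc: empty buried patch")
  core <- function(sd, inp) {
    if (band_trim <= 0 || all(inp)) return(inp)
    spacing <- 2 * sqrt(1 / density)
    d2 <- cross_dist2(sd$dots[inp, , drop = FALSE],
                      sd$dots[!inp, , drop = FALSE])
    boundary <- apply(d2, 1, min) < spacing^2
    if (!any(boundary)) return(inp)
    d2b <- cross_dist2(sd$dots[inp, , drop = FALSE],
                       sd$dots[inp, , drop = FALSE][boundary, , drop = FALSE])
    keep <- apply(d2b, 1, min) > band_trim^2
    keep[boundary] <- FALSE
    out <- inp
    out[inp] <- keep
    out
  }
  ca <- core(sa, ina); cb <- core(sb, inb)
  if (!any(ca)) ca <- ina           # band trim ate the patch: fall back
  if (!any(cb)) cb <- inb
  (sc_half(sa, ca, sb, inb, w) + sc_half(sb, cb, sa, ina, w)) / 2
}

sc_half <- function(sd_self, core_self, sd_other, patch_other, w) {
  da <- sd_self$dots[core_self, , drop = FALSE]
  na <- sd_self$normals[core_self, , drop = FALSE]
  db <- sd_other$dots[patch_other, , drop = FALSE]
  nb <- sd_other$normals[patch_other, , drop = FALSE]
  d2 <- cross_dist2(da, db)
  jn <- max.col(-d2, ties.method = "first")
  d2min <- d2[cbind(seq_len(nrow(da)), jn)]
  dotn <- rowSums(na * -nb[jn, , drop = FALSE])
  stats::median(exp(-w * d2min) * dotn)
}

# Polar heavy atoms able to donate/accept hydrogen bonds (heavy-atom proxy:
# donor hydrogens are waived). Backbone N and O are always polar.
POLAR_SIDECHAIN <- list(
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"), SER = "OG", THR = "OG1",
  TYR = "OH", HIS = c("ND1", "NE2"), TRP = "NE1", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

is_polar_atom <- function(resid, name) {
  name %in% c("N", "O") |
    mapply(function(r, nm) nm %in% (POLAR_SIDECHAIN[[r]] %||% character()),
           resid, name, USE.NAMES = FALSE)
}

#' Buried unsatisfied polar residue count at an interface
#'
#' Counts interface residues (any heavy atom within `interface_cutoff` of
#' the partner subunit) possessing at least one polar heavy atom that is
#' buried in the complex (per-atom SASA below `burial_sasa`) and has no
#' other polar heavy atom within `d_max` (heavy-atom hydrogen-bond proxy;
#' donor hydrogen geometry is waived). Residues are counted across both
#' subunits of the pair.
#'
#' @inheritParams interface_area
#' @param d_max hydrogen-bond heavy-atom distance, Angstrom.
#' @param burial_sasa per-atom SASA (Angstrom^2, in the complex) below which
#'   an atom counts as buried.
#' @param interface_cutoff heavy-atom distance defining interface residues.
#' @param n_points quadrature points per sphere for the burial SASA.
#' @return non-negative integer.
#' @export
unsat_polar_count <- function(f, i, j, d_max = 3.5, burial_sasa = 5,
                              interface_cutoff = 4.5, n_points = 960) {
  p <- pair_subunits(f, i, j)
  comb <- rbind(p$a, p$b)
  xyz <- as.matrix(comb[, c("x", "y", "z")])
  side <- rep(c("a", "b"), c(nrow(p$a), nrow(p$b)))
  areas <- sasa_xyz(xyz, vdw_radius(comb$element), 1.4, n_points)
  d2ab <- cross_dist2(as.matrix(p$a[, c("x", "y", "z")]),
                      as.matrix(p$b[, c("x", "y", "z")]))
  near_a <- apply(d2ab, 1, min) <= interface_cutoff^2
  near_b <- apply(d2ab, 2, min) <= interface_cutoff^2
  at_iface <- c(near_a, near_b)
  reskey <- paste(side, comb$chain, comb$resno)
  iface_res <- unique(reskey[at_iface])
  polar <- is_polar_atom(comb$resid, comb$name)
  count <- 0L
  for (rk in iface_res) {
    idx <- which(reskey == rk & polar)
    if (!length(idx)) next
    unsat <- FALSE
    for (ai in idx) {
      if (areas[ai] >= burial_sasa) next        # exposed: solvent satisfies it
      partners <- which(polar & reskey != rk)
      if (!length(partners)) { unsat <- TRUE; break }
      d2 <- colSums((t(xyz[partners, , drop = FALSE]) - xyz[ai, ])^2)
      if (min(d2) > d_max^2) { unsat <- TRUE; break }
    }
    if (unsat) count <- count + 1L
  }
  count
}

#' Contact pseudo-energy gap of a subunit in its filament context
#'
#' Bound-minus-unbound energy of subunit `i`: each inter-subunit heavy-atom
#' pair within `contact_cutoff` contributes -1 unit, capped at -3 per
#' residue pair, and each clashing pair (closer than `clash_cutoff`) adds
#' +10. The rigid unbound monomer is the zero of energy, so the gap is the
#' (negative) inter-subunit contact energy; 0 for an isolated subunit. The
#' absolute scale is a package convention, not a force-field energy.
#'
#' @param f a `filament` or multi-chain [structure3d].
#' @param i subunit (chain) index, 1-based.
#' @param contact_cutoff,clash_cutoff heavy-atom cutoffs, Angstrom.
#' @return energy gap in surrogate units (negative favours assembly).
#' @export
energy_gap <- function(f, i, contact_cutoff = 4.5, clash_cutoff = 2.4) {
  if (inherits(f, "filament")) f <- f$structure
  ids <- chain_ids(f)
  if (i < 1 || i > length(ids)) stopf("subunit index out of range")
  at <- f$atoms[toupper(f$atoms$element) != "H", , drop = FALSE]
  ai <- at[at$chain == ids[i], , drop = FALSE]
  xi <- as.matrix(ai[, c("x", "y", "z")])
  total <- 0
  for (ch in setdiff(ids, ids[i])) {
    aj <- at[at$chain == ch, , drop = FALSE]
    d2 <- cross_dist2(xi, as.matrix(aj[, c("x", "y", "z")]))
    hit <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    clash <- d2[hit] < clash_cutoff^2
    total <- total + 10 * sum(clash)
    ok <- hit[!clash, , drop = FALSE]
    if (nrow(ok)) {
      respair <- paste(ai$resno[ok[, 1]], aj$resno[ok[, 2]])
      per <- table(respair)
      total <- total - sum(pmin(per, 3))
    }
  }
  total
}

#' Design filter thresholds
#'
#' The four acceptance criteria applied to design records, all strict
#' inequalities: energy gap below `max_energy_gap` (default -15 units),
#' buried interface area above `min_area` (700 Angstrom^2), shape
#' complementarity above `min_sc` (0.62), and unsatisfied-polar count below
#' `max_unsat` (5, exclusive).
#'
#' @param max_energy_gap,min_area,min_sc,max_unsat threshold values.
#' @return named list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(max_energy_gap = -15, min_area = 700,
                              min_sc = 0.62, max_unsat = 5) {
  if (min_area <= 0) stopf("min_area must be positive")
  if (min_sc <= 0 || min_sc >= 1) stopf("min_sc must lie in (0, 1)")
  structure(list(max_energy_gap = max_energy_gap, min_area = min_area,
                 min_sc = min_sc, max_unsat = max_unsat),
            class = "filter_thresholds")
}

RECORD_COLS <- c("energy_gap", "buried_area", "sc", "unsat_count")

#' Apply the design filter pipeline to a record table
#'
#' A record survives iff `energy_gap < max_energy_gap` AND
#' `buried_area > min_area` AND `sc > min_sc` AND `unsat_count < max_unsat`
#' (all strict). The attrition report gives the count removed by each
#' criterion applied independently to the input, plus the joint survivor
#' count.
#'
#' @param records data.frame with columns `energy_gap`, `buried_area`, `sc`,
#'   `unsat_count` (and usually `design_id`, `dock_id`).
#' @param th a [filter_thresholds].
#' @return list with `survivors` (data.frame) and `report` (named list:
#'   per-criterion independent attrition, input size, joint survivors).
#' @export
apply_filters <- function(records, th = filter_thresholds()) {
  miss <- setdiff(RECORD_COLS, names(records))
  if (length(miss))
    stopf("record table missing column(s): %s", paste(miss, collapse = ", "))
  pass_e <- records$energy_gap < th$max_energy_gap
  pass_a <- records$buried_area > th$min_area
  pass_s <- records$sc > th$min_sc
  pass_u <- records$unsat_count < th$max_unsat
  keep <- pass_e & pass_a & pass_s & pass_u
  list(survivors = records[keep, , drop = FALSE],
       report = list(input = nrow(records),
                     removed_energy_gap = sum(!pass_e),
                     removed_buried_area = sum(!pass_a),
                     removed_sc = sum(!pass_s),
                     removed_unsat = sum(!pass_u),
                     survivors = sum(keep)))
}

#' Select the top-scoring design per docked configuration
#'
#' One record per `dock_id`: the minimal `energy_gap`, ties broken by
#' lexical `design_id`.
#'
#' @param records data.frame with `dock_id`, `design_id`, `energy_gap`.
#' @return data.frame, one row per dock, in dock_id order.
#' @export
select_top_per_dock <- function(records) {
  for (col in c("dock_id", "design_id", "energy_gap"))
    if (!col %in% names(records)) stopf("record table missing column: %s", col)
  if (!nrow(records)) return(records)
  ord <- order(records$dock_id, records$energy_gap, records$design_id)
  r <- records[ord, , drop = FALSE]
  out <- r[!duplicated(r$dock_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
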