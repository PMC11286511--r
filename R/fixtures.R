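#' Synthetic helical-bundle subunit generator
#'
#' Builds an idealized poly-alanine helical-bundle subunit: `n_helices`
#' ideal alpha-helices (backbone N, CA, C, O plus CB, ~1.5 Angstrom rise and
#' ~100 degrees of rotation per residue) arranged on a circle of radius
#' `bundle_radius`, alternating up/down as in an antiparallel bundle. The
#' default of three helices mirrors a trimer-derived monomer in which three
#' protomers have been connected into one chain. The subunit is a stand-in
#' for design-stage models: poly-alanine, hydrogen-free, CB present so that
#' burial and contact metrics are meaningful.
#'
#' The generator is a pure function of its arguments: repeated calls with the
#' same spec and seed give bit-identical coordinates. The seed only sets each
#' helix's spin about its own axis.
#'
#' @param n_helices number of helices (>= 1; default 3).
#' @param residues_per_helix residues per helix (>= 4).
#' @param bundle_radius circle radius on which helix axes sit, Angstrom.
#' @param seed integer seed.
#' @return a [structure3d] (single chain "A", residues numbered consecutively).
#' @examples
#' s <- make_bundle_subunit(3, 20, 7, seed = 1)
#' n_atoms(s)  # 3 * 20 * 5
#' @export
make_bundle_subunit <- function(n_helices = 3, residues_per_helix = 20,
                                bundle_radius = 7, seed = 1) {
  if (n_helices < 1) stopf("n_helices must be >= 1")
  if (residues_per_helix < 4) stopf("residues_per_helix must be >= 4")
  if (bundle_radius < 0) stopf("bundle_radius must be non-negative")
  spins <- with_seed(seed, stats::runif(n_helices, 0, 360))
  one <- align_helix_z(backbone_atoms(
    build_backbone(residues_per_helix, HELIX_PHI, HELIX_PSI)))
  parts <- vector("list", n_helices)
  for (k in seq_len(n_helices)) {
    at <- one
    xyz <- as.matrix(at[, c("x", "y", "z")])
    xyz <- xyz %*% t(rot_z(spins[k]))
    if (k %% 2 == 0) xyz <- xyz %*% t(rot_axis(c(1, 0, 0), 180))  # flip down
    ang <- 2 * pi * (k - 1) / n_helices
    xyz[, 1] <- xyz[, 1] + bundle_radius * cos(ang)
    xyz[, 2] <- xyz[, 2] + bundle_radius * sin(ang)
    at[, c("x", "y", "z")] <- xyz
    at$resno <- at$resno + (k - 1L) * residues_per_helix
    parts[[k]] <- at
  }
  atoms <- do.call(rbind, parts)
  s <- structure3d(atoms, metadata = list(
    generator = "make_bundle_subunit",
    n_helices = n_helices, residues_per_helix = residues_per_helix,
    bundle_radius = bundle_radius, seed = seed))
  if (n_helices > 1) {
    helix_of <- rep(seq_len(n_helices), each = residues_per_helix * 5L)
    xyz <- coords(s)
    for (a in seq_len(n_helices - 1)) for (b in seq((a + 1), n_helices)) {
      if (min_dist(xyz[helix_of == a, ], xyz[helix_of == b, ]) <= 2.4)
        stopf("generated bundle has an inter-helix clash (< 2.4 A); increase bundle_radius")
    }
  }
  s
}

#' Preset generating transforms
#'
#' Registry of named screw transforms. `"DpHF19"` stores the deposited
#' filament symmetry of the DpHF19 fibre: an axial rise of 8.4 Angstrom and
#' a rotation of -148.9 degrees per subunit about +z (a left-handed per-step
#' rotation under the package's rise-positive, right-hand-rule convention).
#' `"identity"` is the null transform.
#'
#' @param name preset name, one of `"DpHF19"`, `"identity"`.
#' @return list with `name`, `transform` (a [rigid_transform]), `rise`,
#'   `twist`, and `notes`.
#' @export
get_preset <- function(name) {
  presets <- list(
    DpHF19 = list(rise = 8.4, twist = -148.9,
                  notes = "DpHF19 one-start filament symmetry (cryo-EM)"),
    identity = list(rise = 0, twist = 0, notes = "null transform"))
  if (!name %in% names(presets))
    stopf("unknown preset '%s'; available: %s", name,
          paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  list(name = name,
       transform = rigid_transform(rot_z(p$twist), c(0, 0, p$rise)),
       rise = p$rise, twist = p$twist, notes = p$notes)
}

#' Synthetic design-record table
#'
#' Generates `n` design records whose metric columns are drawn from uniform
#' ranges chosen to straddle every filter threshold, so the four-criterion
#' filter partitions the table non-trivially: energy gap U(-30, 0), buried
#' interface area U(300, 1200) Angstrom^2, shape complementarity U(0.3, 0.9),
#' unsatisfied-polar count uniform on 0..10. A `dock_id` column groups
#' records into docked configurations (about 10 designs per dock).
#'
#' @param n number of records (>= 0).
#' @param seed integer seed; tables are reproducible per seed.
#' @return data.frame with columns `design_id`, `dock_id`, `energy_gap`,
#'   `buried_area`, `sc`, `unsat_count`.
#' @export
make_design_records <- function(n, seed = 1) {
  if (n < 0) stopf("n must be >= 0")
  if (n == 0) {
    return(data.frame(design_id = character(), dock_id = character(),
                      energy_gap = numeric(), buried_area = numeric(),
                      sc = numeric(), unsat_count = integer(),
                      stringsAsFactors = FALSE))
  }
  n_docks <- max(1L, ceiling(n / 10))
  with_seed(seed, {
    data.frame(
      design_id = sprintf("design_%05d", seq_len(n)),
      dock_id = sprintf("dock_%04d", sample.int(n_docks, n, replace = TRUE)),
      energy_gap = stats::runif(n, -30, 0),
      buried_area = stats::runif(n, 300, 1200),
      sc = stats::runif(n, 0.3, 0.9),
      unsat_count = sample(0:10, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Synthetic fragment database generator
#'
#' Miniature analogue of a backbone-fragment database spanning two helical
#' regions: every fragment is a short poly-alanine backbone (N, CA, C, O) of
#' 3 to 8 residues whose first and last residues carry ideal helical torsions
#' (helical caps), with torsions in between drawn from broad loop-like
#' ranges. Deterministic per seed.
#'
#' @param n_fragments number of fragments (>= 1).
#' @param seed integer seed.
#' @return object of class `"fragment_db"`: list of fragments, each with
#'   `id`, `length` (residues), and `coords` (data.frame resno/atom/x/y/z).
#' @export
make_fragment_db <- function(n_fragments, seed = 1) {
  if (n_fragments < 1) stopf("n_fragments must be >= 1")
  frags <- with_seed(seed, {
    lens <- sample(3:8, n_fragments, replace = TRUE)
    lapply(seq_len(n_fragments), function(i) {
      L <- lens[i]
      phi <- stats::runif(L, -150, -50)
      psi <- stats::runif(L, -70, 10)
      phi[c(1, L)] <- HELIX_PHI
      psi[c(1, L)] <- HELIX_PSI
      bb <- build_backbone(L, phi, psi, cb = FALSE)
      make_fragment(sprintf("frag_%04d", i), bb)
    })
  })
  new_fragment_db(frags)
}

make_fragment <- function(id, bb) {
  n <- nrow(bb$N)
  cf <- do.call(rbind, lapply(seq_len(n), function(r) {
    data.frame(resno = r, atom = c("N", "CA", "C", "O"),
               x = c(bb$N[r, 1], bb$CA[r, 1], bb$C[r, 1], bb$O[r, 1]),
               y = c(bb$N[r, 2], bb$CA[r, 2], bb$C[r, 2], bb$O[r, 2]),
               z = c(bb$N[r, 3], bb$CA[r, 3], bb$C[r, 3], bb$O[r, 3]),
               stringsAsFactors = FALSE)
  }))
  list(id = id, length = n, coords = cf)
}

new_fragment_db <- function(fragments) {
  ids <- vapply(fragments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("fragment ids must be unique")
  for (f in fragments) {
    if (f$length < 3) stopf("fragment %s has < 3 residues", f$id)
    per <- table(f$coords$resno)
    if (any(per < 3)) stopf("fragment %s has incomplete backbone", f$id)
  }
  structure(list(fragments = fragments), class = "fragment_db")
}

#' @export
print.fragment_db <- function(x, ...) {
  lens <- vapply(x$fragments, `[[`, integer(1), "length")
  cat(sprintf("fragment_db: %d fragments, %d-%d residues\n",
              length(x$fragments), min(lens), max(lens)))
  invisible(x)
}

#' @rdname make_fragment_db
#' @param db a `fragment_db`.
#' @param path JSON file path.
#' @export
write_fragment_db <- function(db, path) {
  jsonlite::write_json(lapply(db$fragments, function(f)
    list(id = f$id, length = f$length, coords = f$coords)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_fragment_db
#' @export
read_fragment_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_fragment_db(lapply(seq_len(nrow(raw)), function(i)
    list(id = raw$id[i], length = as.integer(raw$length[i]),
         coords = as.data.frame(raw$coords[[i]]))))
}
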