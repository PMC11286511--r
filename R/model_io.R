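#' Minimal atomic structure model
#'
#' A `structure3d` holds an ordered atom table with one row per atom:
#' `name` (atom label), `element`, `x`, `y`, `z` (Angstrom), `resno`
#' (1-based residue index), `resid` (3-letter residue name), and `chain`.
#' Coordinates use a right-handed frame; the filament axis convention
#' throughout the package is +z.
#'
#' @param atoms data.frame with the columns above.
#' @param metadata optional named list of free-form metadata.
#' @param validate set FALSE to skip invariant checks (internal use).
#' @return object of class `"structure3d"`.
#' @export
structure3d <- function(atoms = empty_atoms(), metadata = list(),
                        validate = TRUE) {
  need <- c("name", "element", "x", "y", "z", "resno", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stopf("atom table missing column(s): %s", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$resid <- as.character(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  if (validate && nrow(atoms)) {
    if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stopf("atom coordinates must be finite")
    if (any(!nzchar(atoms$element)))
      stopf("every atom needs a non-empty element symbol")
    key <- paste(atoms$chain, atoms$resno, atoms$name)
    if (anyDuplicated(key))
      stopf("duplicate atom identity (chain, resno, name): %s",
            key[anyDuplicated(key)])
    for (ch in unique(atoms$chain)) {
      r <- atoms$resno[atoms$chain == ch]
      if (is.unsorted(r))
        stopf("residue indices in chain %s are not non-decreasing", ch)
    }
  }
  structure(list(atoms = atoms, metadata = metadata), class = "structure3d")
}

empty_atoms <- function() {
  data.frame(name = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             resno = integer(), resid = character(), chain = character(),
             stringsAsFactors = FALSE)
}

#' @rdname structure3d
#' @param s a `structure3d`.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' @rdname structure3d
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' @rdname structure3d
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

set_coords <- function(s, xyz) {
  s$atoms[, c("x", "y", "z")] <- xyz
  s
}

heavy <- function(s) {
  keep <- toupper(s$atoms$element) != "H"
  structure3d(s$atoms[keep, , drop = FALSE], s$metadata, validate = FALSE)
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d chain(s) [%s], %d residues\n",
              nrow(x$atoms), length(chain_ids(x)),
              paste(chain_ids(x), collapse = ","),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

guess_element <- function(name) {
  # PDB atom-name heuristic: strip digits/primes, two-letter elements only
  # for common hetero cases; designed models are C/N/O/S (+H).
  n <- gsub("[0-9']", "", toupper(trimws(name)))
  first <- substr(n, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, first)
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Parsing goes through bio3d; all ATOM/HETATM coordinate records are kept,
#' coordinates exactly as stored (Angstrom). Alternate locations are resolved
#' deterministically: the highest-occupancy altloc is kept, ties broken by
#' first occurrence, and the choice is recorded in `metadata$altloc`.
#'
#' @param path input file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension, default).
#' @return a [structure3d].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "pdb") check_pdb_lines(path)
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stopf("parse error in '%s': %s", path, conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) return(structure3d())
  elem <- at$elesy
  if (is.null(elem)) elem <- rep("", nrow(at))
  elem <- trimws(as.character(elem))
  noelem <- !nzchar(elem) | is.na(elem)
  elem[noelem] <- guess_element(at$elety[noelem])
  ch <- as.character(at$chain)
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  atoms <- data.frame(name = trimws(at$elety), element = elem,
                      x = at$x, y = at$y, z = at$z,
                      resno = at$resno, resid = trimws(at$resid),
                      chain = ch, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("parse error in '%s': non-numeric coordinate field", path)
  meta <- list(source = path, format = format)
  key <- paste(ch, at$resno, trimws(at$elety))
  if (anyDuplicated(key)) {            # altloc copies of the same atom
    occ <- at$o
    if (is.null(occ)) occ <- rep(1, nrow(atoms))
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(atoms)))  # best occupancy, then first
    keep_rows <- sort(ord[!duplicated(key[ord])])
    atoms <- atoms[keep_rows, , drop = FALSE]
    meta$altloc <- "kept highest-occupancy altloc, ties by first occurrence"
  }
  structure3d(atoms, metadata = meta)
}

# Fail early, naming the offending line, when a PDB coordinate field is
# not numeric (bio3d would silently produce NA).
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM |HETATM)", lines)
  for (i in which(rec)) {
    for (rng in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- substr(lines[i], rng[1], rng[2])
      if (is.na(suppressWarnings(as.numeric(fld))))
        stopf("parse error at line %d of '%s': non-numeric coordinate field '%s'",
              i, path, trimws(fld))
    }
  }
  invisible(TRUE)
}

#' Write an atomic structure to PDB or mmCIF
#'
#' PDB output is produced through bio3d and is limited to 99,999 atoms,
#' single-character chain ids, and coordinates below 10,000 Angstrom in
#' magnitude (field width); mmCIF (hand-written minimal `atom_site` loop)
#' has none of these limits. `read_structure(write_structure(s))` preserves
#' atom order, names, residue numbering, and coordinates to format precision
#' (1e-3 Angstrom for PDB).
#'
#' @param s a [structure3d].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  at <- s$atoms
  if (format == "pdb") {
    if (nrow(at) > 99999L)
      stopf(">99,999 atoms cannot be written as PDB; use format = 'mmcif'")
    if (nrow(at) && any(nchar(at$chain) > 1L))
      stopf("multi-character chain ids cannot be written as PDB; use format = 'mmcif'")
    if (nrow(at) && max(abs(as.matrix(at[, c("x", "y", "z")]))) >= 1e4)
      stopf("coordinate magnitude >= 1e4 A overflows the PDB field; use format = 'mmcif'")
    if (nrow(at) == 0L) {
      writeLines("END", path)
      return(invisible(path))
    }
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resid,
                     eleno = seq_len(nrow(at)), elety = at$name,
                     chain = at$chain, elesy = at$element,
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  } else {
    # standard 21-field atom_site loop (PDB exchange dictionary order)
    hdr <- c("data_helifil",
             "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    rows <- if (nrow(at)) sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      seq_len(nrow(at)), at$element, at$name, at$resid, at$chain,
      at$resno, at$x, at$y, at$z, at$resno, at$resid, at$chain,
      at$name) else character()
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Extract one chain from a structure
#'
#' @param s a [structure3d].
#' @param chain_id chain identifier to extract.
#' @return a [structure3d] with only that chain's atoms, order preserved.
#' @export
extract_chain <- function(s, chain_id) {
  av <- chain_ids(s)
  if (!chain_id %in% av)
    stopf("chain '%s' not present; available: %s", chain_id,
          paste(av, collapse = ", "))
  structure3d(s$atoms[s$atoms$chain == chain_id, , drop = FALSE], s$metadata)
}
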