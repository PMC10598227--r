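#' Coordinate structure
#'
#' A single conformer: an ordered atom table with chain, residue number,
#' residue name, atom name, element and Cartesian coordinates in Angstrom.
#' The (chain, residue number, atom name) triple must be unique and all
#' coordinates finite.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atname`, `x`, `y`, `z`; optional `element` (derived from the atom name
#'   when absent) and logical `het` (written as HETATM records; default
#'   `FALSE`).
#' @param model_id Integer model identifier.
#' @return An object of class `nmr_structure`.
#' @export
nmr_structure <- function(atoms, model_id = 1L) {
  need <- c("chain", "resno", "resname", "atname", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms table must have columns: ", paste(need, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- as.character(atoms$resname)
  atoms$atname <- as.character(atoms$atname)
  if (is.null(atoms$element))
    atoms$element <- ifelse(is_hydrogen_name(atoms$atname), "H",
                            substr(sub("^[0-9]+", "", atoms$atname), 1L, 1L))
  if (is.null(atoms$het)) atoms$het <- FALSE
  key <- paste(atoms$chain, atoms$resno, atoms$atname)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atname): ", key[duplicated(key)][1L])
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite")
  rownames(atoms) <- NULL
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "nmr_structure")
}

#' Coordinate matrix of a structure
#'
#' @param structure An [nmr_structure()].
#' @return Numeric n-by-3 matrix of coordinates (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#'
#' @param structure An [nmr_structure()].
#' @param xyz n-by-3 numeric matrix.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3L)
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

#' @export
print.nmr_structure <- function(x, ...) {
  cat(sprintf("<nmr_structure model %d: %d atoms, %d residues, chains %s>\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

atom_identity <- function(structure) {
  with(structure$atoms, paste(chain, resno, resname, atname))
}

#' Conformer ensemble
#'
#' An ordered list of conformers sharing one atom-identity sequence, e.g.
#' the 20 lowest-energy structures selected from a simulated-annealing pool.
#'
#' @param models List of [nmr_structure()]s with identical atom tables
#'   (identity columns; coordinates differ).
#' @return An object of class `nmr_ensemble`.
#' @export
nmr_ensemble <- function(models) {
  if (length(models) < 1L) stop("an ensemble needs at least one model")
  ids <- atom_identity(models[[1L]])
  for (m in seq_along(models)) {
    if (!inherits(models[[m]], "nmr_structure"))
      stop("model ", m, " is not an nmr_structure")
    if (!identical(atom_identity(models[[m]]), ids))
      stop("model ", m, " has a different atom identity sequence")
    models[[m]]$model_id <- m
  }
  structure(list(models = models), class = "nmr_ensemble")
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat(sprintf("<nmr_ensemble: %d models x %d atoms>\n",
              length(x$models), nrow(x$models[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.nmr_ensemble <- function(x) length(x$models)

#' Read a (multi-model) structure file
#'
#' Reads PDB (via [bio3d::read.pdb()]) or mmCIF (via [bio3d::read.cif()]).
#' Each MODEL record becomes one conformer; a file without MODEL records
#' yields a single-model ensemble. HETATM ligand atoms are retained with
#' their chain/residue identity. Atom order must be consistent across
#' models.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"` or `"cif"`.
#' @return An [nmr_ensemble()].
#' @export
read_structure <- function(path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty coordinate file: ", path)
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  } else {
    bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
  }
  at <- pdb$atom
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resname = as.character(at$resid),
                      atname = as.character(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      element = as.character(at$elesy),
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("model 1 atom count disagrees with the atom table in ", path)
  models <- lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    if (anyNA(co))
      stop("inconsistent atom count in model ", m, " of ", path)
    s <- nmr_structure(atoms, model_id = m)
    set_coords(s, co)
  })
  nmr_ensemble(models)
}

format_pdb_atname <- function(atname, element) {
  ifelse(nchar(atname) >= 4L | nchar(element) == 2L,
         formatC(atname, width = -4L),
         paste0(" ", formatC(atname, width = -3L)))
}

pdb_atom_lines <- function(structure) {
  at <- structure$atoms
  if (any(abs(c(at$x, at$y, at$z)) > 9999.999))
    stop("coordinates exceed the PDB fixed-width field (|x| > 9999.999)")
  rec <- ifelse(at$het, "HETATM", "ATOM  ")
  sprintf("%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(at)),
          format_pdb_atname(at$atname, at$element),
          at$resname, at$chain, at$resno, at$x, at$y, at$z, 1, 0,
          at$element)
}

#' Write a structure or ensemble as PDB
#'
#' Multi-model ensembles are written as MODEL/ENDMDL blocks; coordinates are
#' fixed-width with three decimals, so a read/write round trip preserves
#' identities exactly and coordinates to 0.001 Angstrom.
#'
#' @param x An [nmr_structure()] or [nmr_ensemble()].
#' @param path Output path.
#' @param header Optional character vector of REMARK lines (provenance).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, header = NULL) {
  if (inherits(x, "nmr_structure")) x <- nmr_ensemble(list(x))
  stopifnot(inherits(x, "nmr_ensemble"))
  out <- character(0L)
  if (!is.null(header)) out <- paste("REMARK  ", header)
  multi <- length(x$models) > 1L
  for (m in seq_along(x$models)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, pdb_atom_lines(x$models[[m]]))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
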