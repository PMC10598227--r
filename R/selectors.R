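#' Atom selector
#'
#' A selector identifies one atom, or a pseudoatom group of atoms, inside a
#' structure: a chain, a 1-based residue number, optionally a residue name,
#' and an atom-name pattern. The pattern is either an exact atom name
#' (`"HZ"`) or a trailing-wildcard pseudoatom pattern (`"HD1*"`), the
#' convention used for degenerate protons such as methyl groups.
#'
#' @param chain_id Chain identifier (single string).
#' @param residue_number 1-based residue number as it appears in the
#'   coordinate file.
#' @param atom_pattern Exact atom name or trailing-wildcard pattern; at most
#'   one `*`, and only in terminal position.
#' @param residue_name Optional three-letter residue name used for
#'   consistency checks against coordinates.
#' @return An object of class `atom_selector`.
#' @examples
#' atom_selector("A", 71, "HE*", "PHE")
#' @export
atom_selector <- function(chain_id, residue_number, atom_pattern,
                          residue_name = NA_character_) {
  chain_id <- as.character(chain_id)
  residue_number <- as.integer(residue_number)
  atom_pattern <- as.character(atom_pattern)
  stopifnot(length(chain_id) == 1L, length(residue_number) == 1L,
            length(atom_pattern) == 1L)
  if (is.na(atom_pattern) || !nzchar(atom_pattern))
    stop("atom_pattern must be non-empty")
  n_star <- lengths(regmatches(atom_pattern, gregexpr("\\*", atom_pattern)))
  if (n_star > 1L)
    stop("atom_pattern may contain at most one wildcard: ", atom_pattern)
  if (n_star == 1L && !endsWith(atom_pattern, "*"))
    stop("wildcard is only allowed in terminal position: ", atom_pattern)
  if (is.na(residue_number) || residue_number < 1L)
    stop("residue_number must be >= 1")
  structure(list(chain_id = chain_id, residue_number = residue_number,
                 residue_name = as.character(residue_name),
                 atom_pattern = atom_pattern),
            class = "atom_selector")
}

#' @export
print.atom_selector <- function(x, ...) {
  rn <- if (is.na(x$residue_name)) "" else paste0(" ", x$residue_name)
  cat(sprintf("<atom_selector %s:%d%s %s>\n", x$chain_id, x$residue_number,
              rn, x$atom_pattern))
  invisible(x)
}

#' @export
format.atom_selector <- function(x, ...) {
  sprintf("%s/%d/%s", x$chain_id, x$residue_number, x$atom_pattern)
}

# TRUE where atom names match an exact-or-trailing-wildcard pattern
match_atom_pattern <- function(pattern, names) {
  if (endsWith(pattern, "*")) {
    startsWith(names, substr(pattern, 1L, nchar(pattern) - 1L))
  } else {
    names == pattern
  }
}

#' Indices of the atoms matched by a selector
#'
#' @param selector An [atom_selector()].
#' @param structure An [nmr_structure()].
#' @return Integer vector of row indices into the structure's atom table, in
#'   file order (possibly empty).
#' @export
match_atoms <- function(selector, structure) {
  at <- structure$atoms
  hit <- at$chain == selector$chain_id &
    at$resno == selector$residue_number &
    match_atom_pattern(selector$atom_pattern, at$atname)
  which(hit)
}

#' Expand a selector pair into explicit atom-index pairs
#'
#' Pseudoatom selectors (e.g. `HD1*`) match several protons; a restraint
#' between two selectors is evaluated over the Cartesian product of the two
#' match sets, in file order.
#'
#' @param sel_i,sel_j [atom_selector()]s for the two sides.
#' @param structure An [nmr_structure()].
#' @return Two-column integer matrix (columns `i`, `j`), one row per pair.
#' @export
expand_pair <- function(sel_i, sel_j, structure) {
  ai <- match_atoms(sel_i, structure)
  aj <- match_atoms(sel_j, structure)
  if (length(ai) == 0L)
    stop("selector matches no atoms: ", format(sel_i))
  if (length(aj) == 0L)
    stop("selector matches no atoms: ", format(sel_j))
  g <- expand.grid(j = aj, i = ai, KEEP.OUT.ATTRS = FALSE)
  cbind(i = g$i, j = g$j)
}

BACKBONE_ATOMS  <- c("N", "CA", "C", "O")
BACKBONE3_ATOMS <- c("N", "CA", "C")

#' Residue-range / atom-set selection
#'
#' Selections name inclusive residue ranges on one chain plus an atom set,
#' mirroring strings such as `"A:10-31,47-176@backbone"`. Atom sets:
#' `"backbone"` (N, CA, C, O), `"backbone3"` (N, CA, C), `"heavy"` (all
#' non-hydrogen atoms), `"all"`, or an explicit character vector of atom
#' names.
#'
#' @param chain Chain identifier.
#' @param ranges Two-column matrix or data.frame of inclusive
#'   `(start, end)` residue ranges; they must not overlap.
#' @param atoms Atom-set keyword or explicit atom-name vector.
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(chain, ranges, atoms = "backbone") {
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2L) stop("ranges must have two columns (start, end)")
  storage.mode(ranges) <- "integer"
  if (any(ranges[, 1L] > ranges[, 2L])) stop("range start exceeds end")
  o <- order(ranges[, 1L])
  ranges <- ranges[o, , drop = FALSE]
  if (nrow(ranges) > 1L &&
      any(ranges[-1L, 1L] <= ranges[-nrow(ranges), 2L]))
    stop("selection ranges overlap")
  colnames(ranges) <- c("start", "end")
  structure(list(chain = as.character(chain), ranges = ranges, atoms = atoms),
            class = "atom_selection")
}

#' Parse a selection string
#'
#' @param text Selection in the form `"A:10-31,47-176@backbone"`; the
#'   `@set` suffix is optional and defaults to `backbone`.
#' @return An [atom_selection()].
#' @export
parse_selection <- function(text) {
  stopifnot(length(text) == 1L, nzchar(text))
  atoms <- "backbone"
  if (grepl("@", text, fixed = TRUE)) {
    parts <- strsplit(text, "@", fixed = TRUE)[[1L]]
    text <- parts[1L]
    atoms <- parts[2L]
  }
  if (!grepl(":", text, fixed = TRUE))
    stop("selection must be 'CHAIN:ranges[@atoms]': ", text)
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  chain <- parts[1L]
  spans <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
  rng <- t(vapply(spans, function(s) {
    ab <- as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    if (anyNA(ab)) stop("malformed residue range: ", s)
    ab
  }, integer(2L)))
  atom_selection(chain, rng, atoms)
}

selection_atom_names <- function(atoms) {
  if (length(atoms) == 1L && atoms %in%
      c("backbone", "backbone3", "heavy", "all")) {
    switch(atoms, backbone = BACKBONE_ATOMS, backbone3 = BACKBONE3_ATOMS,
           heavy = NULL, all = NULL)
  } else {
    atoms
  }
}

is_hydrogen_name <- function(atname) {
  grepl("^[0-9]*H", atname)
}

#' Resolve a selection to atom indices
#'
#' @param selection An [atom_selection()].
#' @param structure An [nmr_structure()].
#' @return Integer vector of atom-table row indices in file order.
#' @export
resolve_selection <- function(selection, structure) {
  at <- structure$atoms
  in_range <- rep(FALSE, nrow(at))
  for (r in seq_len(nrow(selection$ranges))) {
    in_range <- in_range |
      (at$resno >= selection$ranges[r, 1L] &
       at$resno <= selection$ranges[r, 2L])
  }
  keep <- at$chain == selection$chain & in_range
  set <- selection$atoms
  if (length(set) == 1L && set == "heavy") {
    keep <- keep & !is_hydrogen_name(at$atname)
  } else if (!(length(set) == 1L && set == "all")) {
    keep <- keep & at$atname %in% selection_atom_names(set)
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection matches no atoms")
  idx
}
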