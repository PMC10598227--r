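## NOE intensity classes and their fixed interproton-distance bounds (A).
## The lower bound is always 1.8 A (van der Waals contact of two protons).
INTENSITY_CLASSES <- c(strong = 2.8, medium = 3.5, weak = 5.0, very_weak = 6.0)
NOE_LOWER_BOUND <- 1.8

HBOND_HO_BOUNDS <- c(1.7, 2.5)
HBOND_NO_BOUNDS <- c(2.7, 3.5)

#' Distance bounds for an NOE intensity class
#'
#' Cross-peak intensities are classified as strong, medium, weak or very
#' weak and assigned fixed interproton bounds of 1.8-2.8, 1.8-3.5, 1.8-5.0
#' and 1.8-6.0 Angstrom respectively.
#'
#' @param class One of `"strong"`, `"medium"`, `"weak"`, `"very_weak"`.
#' @return Named numeric vector `c(lower, upper)` in Angstrom.
#' @examples
#' classify_intensity("strong")    # 1.8 2.8
#' classify_intensity("very_weak") # 1.8 6.0
#' @export
classify_intensity <- function(class) {
  stopifnot(length(class) == 1L)
  if (!class %in% names(INTENSITY_CLASSES))
    stop("unknown intensity class: '", class, "'")
  c(lower = NOE_LOWER_BOUND, upper = unname(INTENSITY_CLASSES[class]))
}

#' Tightest intensity class containing a distance
#'
#' The inverse of [classify_intensity()]: the tightest class whose upper
#' bound is at least `d`.
#'
#' @param d Distance(s) in Angstrom.
#' @return Character vector of class names.
#' @export
intensity_for_distance <- function(d) {
  vapply(d, function(di) {
    ok <- INTENSITY_CLASSES >= di
    if (!any(ok)) stop("distance ", di, " A exceeds the widest class (6.0 A)")
    names(INTENSITY_CLASSES)[which(ok)[1L]]
  }, character(1L))
}

#' Construct distance restraints
#'
#' A distance restraint ties two (possibly pseudoatom) selectors to a
#' lower/upper bound in Angstrom. NOE restraints have a fixed 1.8 A lower
#' bound; hydrogen-bond restraints carry the fixed H/O or N/O pairs.
#' Restraints are stored as data.frame rows so that sets can be combined
#' with `rbind()` and evaluated vectorially.
#'
#' @param chain_i,resno_i,atom_i,resname_i First selector.
#' @param chain_j,resno_j,atom_j,resname_j Second selector.
#' @param lower,upper Bounds in Angstrom (`0 < lower < upper`). When
#'   `intensity` is given the class bounds are used and `lower`/`upper`
#'   must be omitted.
#' @param origin `"noe"` or `"hbond"`.
#' @param intensity Optional intensity class name, `"unset"` otherwise.
#' @return One-row data.frame of class `distance_restraints`.
#' @export
distance_restraint <- function(chain_i, resno_i, atom_i,
                               chain_j, resno_j, atom_j,
                               lower = NULL, upper = NULL,
                               origin = "noe", intensity = "unset",
                               resname_i = NA_character_,
                               resname_j = NA_character_) {
  if (!identical(intensity, "unset")) {
    if (!is.null(lower) || !is.null(upper))
      stop("give either an intensity class or explicit bounds, not both")
    b <- classify_intensity(intensity)
    lower <- b[["lower"]]
    upper <- b[["upper"]]
  }
  if (is.null(lower) || is.null(upper))
    stop("bounds are required when no intensity class is given")
  if (!(lower > 0 && lower < upper))
    stop("bounds must satisfy 0 < lower < upper (got ", lower, ", ", upper, ")")
  origin <- match.arg(origin, c("noe", "hbond"))
  if (origin == "noe" && abs(lower - NOE_LOWER_BOUND) > 1e-9)
    stop("NOE restraints have a fixed lower bound of 1.8 A")
  # validate the selector fields through the selector constructor
  atom_selector(chain_i, resno_i, atom_i, resname_i)
  atom_selector(chain_j, resno_j, atom_j, resname_j)
  out <- data.frame(chain_i = as.character(chain_i),
                    resno_i = as.integer(resno_i),
                    resname_i = as.character(resname_i),
                    atom_i = as.character(atom_i),
                    chain_j = as.character(chain_j),
                    resno_j = as.integer(resno_j),
                    resname_j = as.character(resname_j),
                    atom_j = as.character(atom_j),
                    lower = as.numeric(lower), upper = as.numeric(upper),
                    origin = origin, intensity = intensity,
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_restraints", "data.frame")
  out
}

distance_restraint_selectors <- function(row) {
  list(atom_selector(row$chain_i[1L], row$resno_i[1L], row$atom_i[1L],
                     row$resname_i[1L]),
       atom_selector(row$chain_j[1L], row$resno_j[1L], row$atom_j[1L],
                     row$resname_j[1L]))
}

empty_distance_restraints <- function() {
  out <- data.frame(chain_i = character(0L), resno_i = integer(0L),
                    resname_i = character(0L), atom_i = character(0L),
                    chain_j = character(0L), resno_j = integer(0L),
                    resname_j = character(0L), atom_j = character(0L),
                    lower = numeric(0L), upper = numeric(0L),
                    origin = character(0L), intensity = character(0L),
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_restraints", "data.frame")
  out
}

#' Construct a dihedral restraint
#'
#' Four ordered selectors, a target angle and a half-width, both in
#' degrees. TALOS-derived restraints have half-widths of at least 20
#' degrees.
#'
#' @param chain Chain shared by the four atoms (backbone torsions are
#'   intra-chain).
#' @param resno Length-4 integer vector of residue numbers.
#' @param atoms Length-4 character vector of atom names, in torsion order.
#' @param target Target angle in degrees, in (-180, 180].
#' @param half_width Half-width of the allowed band in degrees (> 0).
#' @param angle_name `"phi"`, `"psi"` or `"other"`.
#' @return One-row data.frame of class `dihedral_restraints`.
#' @export
dihedral_restraint <- function(chain, resno, atoms, target, half_width,
                               angle_name = "other") {
  stopifnot(length(resno) == 4L, length(atoms) == 4L)
  angle_name <- match.arg(angle_name, c("phi", "psi", "other"))
  if (!(target > -180 && target <= 180) || !is.finite(target))
    stop("target must lie in (-180, 180]")
  if (half_width <= 0) stop("half_width must be positive")
  out <- data.frame(chain = as.character(chain),
                    resno_1 = as.integer(resno[1L]), atom_1 = atoms[1L],
                    resno_2 = as.integer(resno[2L]), atom_2 = atoms[2L],
                    resno_3 = as.integer(resno[3L]), atom_3 = atoms[3L],
                    resno_4 = as.integer(resno[4L]), atom_4 = atoms[4L],
                    target = as.numeric(target),
                    half_width = as.numeric(half_width),
                    angle_name = angle_name, stringsAsFactors = FALSE)
  class(out) <- c("dihedral_restraints", "data.frame")
  out
}

empty_dihedral_restraints <- function() {
  out <- data.frame(chain = character(0L),
                    resno_1 = integer(0L), atom_1 = character(0L),
                    resno_2 = integer(0L), atom_2 = character(0L),
                    resno_3 = integer(0L), atom_3 = character(0L),
                    resno_4 = integer(0L), atom_4 = character(0L),
                    target = numeric(0L), half_width = numeric(0L),
                    angle_name = character(0L), stringsAsFactors = FALSE)
  class(out) <- c("dihedral_restraints", "data.frame")
  out
}

dihedral_restraint_atoms <- function(row, structure) {
  vapply(1:4, function(k) {
    resolve_single_atom(atom_selector(row$chain[1L],
                                      row[[paste0("resno_", k)]][1L],
                                      row[[paste0("atom_", k)]][1L]),
                        structure)
  }, integer(1L))
}

#' Restraint set
#'
#' The container for all restraints of a structure calculation: distance
#' restraints (NOE + hydrogen bond) and dihedral restraints, with a free
#' provenance string.
#'
#' @param distance A `distance_restraints` data.frame (rows combinable with
#'   `rbind`).
#' @param dihedral A `dihedral_restraints` data.frame.
#' @param provenance Free-text origin note.
#' @return An object of class `restraint_set`.
#' @export
restraint_set <- function(distance = empty_distance_restraints(),
                          dihedral = empty_dihedral_restraints(),
                          provenance = "") {
  if (is.null(distance)) distance <- empty_distance_restraints()
  if (is.null(dihedral)) dihedral <- empty_dihedral_restraints()
  rownames(distance) <- NULL
  rownames(dihedral) <- NULL
  structure(list(distance = distance, dihedral = dihedral,
                 provenance = provenance, category_counts = NULL),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set: %d distance, %d dihedral restraints>\n",
              nrow(x$distance), nrow(x$dihedral)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Hydrogen-bond distance restraints
#'
#' Each hydrogen bond contributes exactly two restraints: H/O at
#' 1.7-2.5 Angstrom and N/O at 2.7-3.5 Angstrom. Selectors must be
#' atom-specific (no wildcards).
#'
#' @param pairs data.frame with one row per hydrogen bond and columns
#'   `chain_d`, `resno_d` (donor), `chain_a`, `resno_a` (acceptor);
#'   optional `n_atom`, `h_atom`, `o_atom` atom names (default `N`, `H`,
#'   `O`).
#' @return A `distance_restraints` data.frame with `2 * nrow(pairs)` rows,
#'   origin `"hbond"`.
#' @examples
#' make_hbond_restraints(data.frame(chain_d = "A", resno_d = 5,
#'                                  chain_a = "A", resno_a = 1))
#' @export
make_hbond_restraints <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_distance_restraints())
  if (is.null(pairs$n_atom)) pairs$n_atom <- "N"
  if (is.null(pairs$h_atom)) pairs$h_atom <- "H"
  if (is.null(pairs$o_atom)) pairs$o_atom <- "O"
  nm <- c(pairs$n_atom, pairs$h_atom, pairs$o_atom)
  if (any(grepl("*", nm, fixed = TRUE)))
    stop("hydrogen-bond selectors must be atom-specific (no wildcards)")
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    p <- pairs[r, ]
    rbind(distance_restraint(p$chain_d, p$resno_d, p$h_atom,
                             p$chain_a, p$resno_a, p$o_atom,
                             lower = HBOND_HO_BOUNDS[1L],
                             upper = HBOND_HO_BOUNDS[2L], origin = "hbond"),
          distance_restraint(p$chain_d, p$resno_d, p$n_atom,
                             p$chain_a, p$resno_a, p$o_atom,
                             lower = HBOND_NO_BOUNDS[1L],
                             upper = HBOND_NO_BOUNDS[2L], origin = "hbond"))
  })
  res <- do.call(rbind, out)
  class(res) <- c("distance_restraints", "data.frame")
  res
}

RESTRAINT_CATEGORIES <- c("intra_residue", "sequential", "medium_range",
                          "long_range", "intermolecular", "hydrogen_bond")

#' Categorize distance restraints
#'
#' Assigns each restraint to the standard accounting categories:
#' `hydrogen_bond` for hbond-origin restraints, `intermolecular` when
#' exactly one side sits on the ligand chain, and otherwise by the residue
#' separation |i - j|: 0 intra-residue, 1 sequential, 2-4 medium-range,
#' > 4 long-range.
#'
#' @param restraints A `distance_restraints` data.frame (any number of
#'   rows).
#' @param ligand_chain Chain identifier of the ligand.
#' @return Factor with levels `r toString(RESTRAINT_CATEGORIES)`.
#' @export
categorize <- function(restraints, ligand_chain) {
  if (nrow(restraints) == 0L)
    return(factor(character(0L), levels = RESTRAINT_CATEGORIES))
  on_l_i <- restraints$chain_i == ligand_chain
  on_l_j <- restraints$chain_j == ligand_chain
  both <- which(on_l_i & on_l_j)
  if (length(both) > 0L)
    stop("restraint ", both[1L], " has both sides on the ligand chain '",
         ligand_chain, "'; no intra-ligand restraint protocol is defined")
  sep <- abs(restraints$resno_i - restraints$resno_j)
  cat <- ifelse(restraints$origin == "hbond", "hydrogen_bond",
         ifelse(xor(on_l_i, on_l_j), "intermolecular",
         ifelse(sep == 0L, "intra_residue",
         ifelse(sep == 1L, "sequential",
         ifelse(sep <= 4L, "medium_range", "long_range")))))
  factor(cat, levels = RESTRAINT_CATEGORIES)
}

#' Restraint accounting
#'
#' Category counts and the derived totals used in structure-statistics
#' tables: the NOE total is the sum of the five NOE categories
#' (intra-residue, sequential, medium-range, long-range, intermolecular),
#' the inter-residue total is sequential + medium + long, and the grand
#' total is NOE + dihedral + hydrogen bond.
#'
#' @param x A [restraint_set()], or a named integer vector/list of category
#'   counts (names among `r toString(RESTRAINT_CATEGORIES)` plus optionally
#'   `phi`/`psi` or `dihedral_total`), e.g. a transcribed published
#'   restraint-count manifest.
#' @param ligand_chain Ligand chain identifier (used when `x` is a
#'   restraint set).
#' @return Named integer vector with the six category counts plus
#'   `inter_residue_total`, `noe_total`, `dihedral_total` and
#'   `grand_total`.
#' @export
accounting <- function(x, ligand_chain = "L") {
  if (inherits(x, "restraint_set")) {
    cats <- table(categorize(x$distance, ligand_chain))
    counts <- as.integer(cats[RESTRAINT_CATEGORIES])
    names(counts) <- RESTRAINT_CATEGORIES
    counts[is.na(counts)] <- 0L
    dihedral_total <- nrow(x$dihedral)
  } else {
    x <- unlist(x)
    counts <- stats::setNames(integer(length(RESTRAINT_CATEGORIES)),
                              RESTRAINT_CATEGORIES)
    known <- intersect(names(x), RESTRAINT_CATEGORIES)
    counts[known] <- as.integer(x[known])
    dihedral_total <- if ("dihedral_total" %in% names(x)) {
      as.integer(x[["dihedral_total"]])
    } else {
      sum(as.integer(x[intersect(c("phi", "psi"), names(x))]))
    }
  }
  inter_residue <- sum(counts[c("sequential", "medium_range", "long_range")])
  noe_total <- inter_residue + counts[["intra_residue"]] +
    counts[["intermolecular"]]
  grand <- noe_total + dihedral_total + counts[["hydrogen_bond"]]
  c(counts,
    inter_residue_total = as.integer(inter_residue),
    noe_total = as.integer(noe_total),
    dihedral_total = as.integer(dihedral_total),
    grand_total = as.integer(grand))
}

#' Read a restraint-count manifest
#'
#' A manifest is a two-column whitespace/tab-separated table
#' (`category  count`, `#` comments allowed) transcribing a published
#' restraint-accounting table; [accounting()] reproduces its derived
#' totals.
#'
#' @param path Path to the manifest file.
#' @return Named integer vector of counts.
#' @export
read_restraint_manifest <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("category", "count"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$count), tab$category)
}
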