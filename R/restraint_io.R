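AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA3TO1 <- stats::setNames(names(AA1TO3), AA1TO3)

#' Parse a distance-restraint table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv_table1`}{whitespace- or tab-separated rows
#'     `residue_token protein_hydrogen ligand_hydrogen upper_A` (e.g.
#'     `F71 HE* HM* 4.5`) with `#` comments, the layout of published
#'     intermolecular-NOE tables. The lower bound is fixed at 1.8 A; the
#'     residue-token letter supplies the residue name.}
#'   \item{`cns_tbl`}{CNS-style
#'     `assign (segid S and resid N and name X) (...) d dminus dplus`
#'     records, with bounds reconstructed as `(d - dminus, d + dplus)`.
#'     Only this assign form is supported.}
#' }
#'
#' @param text Character scalar (or vector of lines) holding the table.
#' @param dialect `"tsv_table1"` or `"cns_tbl"`.
#' @param protein_chain,ligand_chain Chains assigned to the two sides of
#'   `tsv_table1` rows (the ligand side is placed on `ligand_chain`,
#'   residue 1).
#' @param ligand_resno Residue number given to the ligand selector.
#' @param methyl_bonus Optional widening (A) added to the upper bound of
#'   restraints whose selectors include a pseudoatom wildcard, a
#'   configuration hook for methyl-specific bound scaling; default 0 (no
#'   inflation).
#' @return A [restraint_set()]; the attribute `"raw_rows"` on the set holds
#'   the number of data rows parsed (reported as-is, reconciliation of any
#'   published count discrepancy is left to the user).
#' @examples
#' parse_distance_table("F71 HE* HM* 4.5", "tsv_table1")
#' @export
parse_distance_table <- function(text, dialect = c("tsv_table1", "cns_tbl"),
                                 protein_chain = "A", ligand_chain = "L",
                                 ligand_resno = 1L, methyl_bonus = 0) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(text) == 0L)
    stop("restraint table text is empty")
  text <- sub("#.*$", "", text)
  lines <- trimws(text)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  rows <- if (dialect == "tsv_table1") {
    parse_tsv_rows(lines, lineno, protein_chain, ligand_chain, ligand_resno)
  } else {
    parse_cns_rows(lines, lineno)
  }
  if (methyl_bonus != 0 && nrow(rows) > 0L) {
    wild <- grepl("*", rows$atom_i, fixed = TRUE) |
      grepl("*", rows$atom_j, fixed = TRUE)
    rows$upper[wild] <- rows$upper[wild] + methyl_bonus
  }
  set <- restraint_set(distance = rows,
                       provenance = paste0("parsed ", dialect, " (",
                                           nrow(rows), " rows)"))
  attr(set, "raw_rows") <- nrow(rows)
  set
}

parse_tsv_rows <- function(lines, lineno, protein_chain, ligand_chain,
                           ligand_resno) {
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "[[:space:]]+")[[1L]]
    if (length(f) != 4L)
      stop("malformed row at line ", lineno[k], ": expected 4 fields, got ",
           length(f))
    tok <- f[1L]
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)$", tok))[[1L]]
    if (length(m) == 0L)
      stop("malformed residue token '", tok, "' at line ", lineno[k])
    resname <- AA1TO3[toupper(m[2L])]
    if (is.na(resname))
      stop("unknown residue letter '", m[2L], "' at line ", lineno[k])
    upper <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(upper))
      stop("malformed upper bound '", f[4L], "' at line ", lineno[k])
    if (upper <= NOE_LOWER_BOUND)
      stop("upper bound ", upper, " <= 1.8 A at line ", lineno[k])
    out[[k]] <- distance_restraint(protein_chain, as.integer(m[3L]), f[2L],
                                   ligand_chain, ligand_resno, f[3L],
                                   lower = NOE_LOWER_BOUND, upper = upper,
                                   resname_i = unname(resname))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_distance_restraints()
  class(res) <- c("distance_restraints", "data.frame")
  res
}

parse_cns_selector <- function(txt, lineno) {
  get1 <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "[[:space:]]+([^[:space:]()]+)"),
                                 txt))[[1L]]
    if (length(m) == 0L)
      stop("missing '", key, "' in selector at line ", lineno)
    m[2L]
  }
  list(chain = get1("segid"), resno = as.integer(get1("resid")),
       atom = get1("name"))
}

parse_cns_rows <- function(lines, lineno) {
  # join continuation lines: an assign record may wrap; re-split on "assign"
  blob <- paste(lines, collapse = " ")
  recs <- strsplit(blob, "(?i)\\bassign\\b", perl = TRUE)[[1L]]
  recs <- trimws(recs)
  recs <- recs[nzchar(recs)]
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    m <- regmatches(recs[k], regexec(
      "^\\(([^()]*)\\)[[:space:]]*\\(([^()]*)\\)[[:space:]]*([-0-9.eE]+)[[:space:]]+([-0-9.eE]+)[[:space:]]+([-0-9.eE]+)",
      recs[k]))[[1L]]
    if (length(m) == 0L)
      stop("malformed assign record ", k, " in CNS table")
    s1 <- parse_cns_selector(m[2L], k)
    s2 <- parse_cns_selector(m[3L], k)
    d <- as.numeric(m[4L]); dminus <- as.numeric(m[5L]); dplus <- as.numeric(m[6L])
    lo <- d - dminus
    up <- d + dplus
    # CNS assign records do not label their origin: the two fixed
    # hydrogen-bond bound pairs are recognized, everything else is an NOE
    hb <- (abs(lo - HBOND_HO_BOUNDS[1L]) < 1e-3 &&
           abs(up - HBOND_HO_BOUNDS[2L]) < 1e-3) ||
          (abs(lo - HBOND_NO_BOUNDS[1L]) < 1e-3 &&
           abs(up - HBOND_NO_BOUNDS[2L]) < 1e-3)
    out[[k]] <- distance_restraint(s1$chain, s1$resno, s1$atom,
                                   s2$chain, s2$resno, s2$atom,
                                   lower = lo, upper = up,
                                   origin = if (hb) "hbond" else "noe")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_distance_restraints()
  class(res) <- c("distance_restraints", "data.frame")
  res
}

#' Write a distance-restraint table
#'
#' Inverse of [parse_distance_table()]; `parse(write(S))` reproduces `S`
#' field-wise for well-formed sets. The `tsv_table1` dialect can only
#' represent protein-ligand NOE rows with the fixed 1.8 A lower bound; the
#' CNS dialect represents any distance restraint (hydrogen-bond origin is
#' not encoded by CNS assign records, so hbond rows round-trip as NOE-form
#' bounds only).
#'
#' @param set A [restraint_set()] (or `distance_restraints` data.frame).
#' @param dialect `"tsv_table1"` or `"cns_tbl"`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to `path`).
#' @export
write_distance_table <- function(set, dialect = c("tsv_table1", "cns_tbl"),
                                 path = NULL) {
  dialect <- match.arg(dialect)
  rows <- if (inherits(set, "restraint_set")) set$distance else set
  lines <- if (dialect == "tsv_table1") {
    if (nrow(rows) > 0L) {
      one <- AA3TO1[rows$resname_i]
      if (anyNA(one))
        stop("tsv_table1 requires a standard residue_name on side i")
      sprintf("%s%d\t%s\t%s\t%g", unname(one), rows$resno_i, rows$atom_i,
              rows$atom_j, rows$upper)
    } else character(0L)
  } else {
    if (nrow(rows) > 0L) {
      d <- (rows$lower + rows$upper) / 2
      dd <- (rows$upper - rows$lower) / 2
      sprintf(paste0("assign (segid %s and resid %d and name %s) ",
                     "(segid %s and resid %d and name %s) %.3f %.3f %.3f"),
              rows$chain_i, rows$resno_i, rows$atom_i,
              rows$chain_j, rows$resno_j, rows$atom_j, d, dd, dd)
    } else character(0L)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Check residue-name consistency of parsed restraints against coordinates
#'
#' Warns (does not error) when a restraint's residue name disagrees with
#' the residue found at that chain/number in the structure.
#'
#' @param set A [restraint_set()].
#' @param structure An [nmr_structure()].
#' @return Invisibly, a data.frame of mismatches (possibly empty).
#' @export
check_restraint_residues <- function(set, structure) {
  rows <- set$distance
  at <- unique(structure$atoms[, c("chain", "resno", "resname")])
  key <- paste(at$chain, at$resno)
  mism <- list()
  for (side in c("i", "j")) {
    rn <- rows[[paste0("resname_", side)]]
    ch <- rows[[paste0("chain_", side)]]
    no <- rows[[paste0("resno_", side)]]
    found <- at$resname[match(paste(ch, no), key)]
    bad <- which(!is.na(rn) & !is.na(found) & rn != found)
    if (length(bad))
      mism[[side]] <- data.frame(row = bad, chain = ch[bad], resno = no[bad],
                                 stated = rn[bad], found = found[bad])
  }
  mism <- if (length(mism)) do.call(rbind, mism) else
    data.frame(row = integer(0L))
  if (nrow(mism) > 0L)
    warning("residue-name mismatch between restraints and coordinates (",
            nrow(mism), " side(s)); see returned table")
  invisible(mism)
}
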