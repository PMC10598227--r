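#' Read a TALOS-style backbone-angle prediction table
#'
#' Whitespace-separated columns `RESID PHI PSI DPHI DPSI CLASS` with `#`
#' comments. Rows whose class is `Good` (case-insensitive; anything else,
#' e.g. `Ambig`/`Bad`/`None`, is unusable) yield usable records.
#'
#' @param path Path to the table, or a character vector of lines via
#'   `text`.
#' @param text Optional literal table text (overrides `path`).
#' @return data.frame with columns `resno`, `phi`, `psi`, `phi_sd`,
#'   `psi_sd`, `usable`.
#' @export
read_talos <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(path)
  tab <- utils::read.table(text = text, header = FALSE, comment.char = "#",
                           col.names = c("resno", "phi", "psi",
                                         "phi_sd", "psi_sd", "class"),
                           stringsAsFactors = FALSE)
  rec <- data.frame(resno = as.integer(tab$resno),
                    phi = as.numeric(tab$phi), psi = as.numeric(tab$psi),
                    phi_sd = as.numeric(tab$phi_sd),
                    psi_sd = as.numeric(tab$psi_sd),
                    usable = tolower(tab$class) == "good",
                    stringsAsFactors = FALSE)
  bad <- !is.na(rec$phi) &
    (rec$phi <= -180 | rec$phi > 180 | rec$psi <= -180 | rec$psi > 180)
  if (any(bad)) stop("angles outside (-180, 180] at residue ",
                     rec$resno[bad][1L])
  if (any(rec$phi_sd < 0 | rec$psi_sd < 0, na.rm = TRUE))
    stop("negative standard deviation in TALOS table")
  rec
}

#' Convert TALOS records to phi/psi dihedral restraints
#'
#' Each usable record yields one phi restraint (atoms C' of the preceding
#' residue, then N, CA, C') and one psi restraint (N, CA, C', then N of the
#' following residue), centred on the predicted angle with half-width
#' `max(min_half_width, sd_factor * sd)` — by default the maximum of 20
#' degrees or 1.5 times the prediction's standard deviation. Records at the
#' chain termini that lack the flanking backbone atom are skipped; the
#' skipped residues are recorded in the `"skipped"` attribute of the result.
#'
#' @param records data.frame from [read_talos()] (columns `resno`, `phi`,
#'   `psi`, `phi_sd`, `psi_sd`, `usable`).
#' @param chain Chain identifier for the backbone atoms.
#' @param residue_range Integer `c(first, last)` residue present in the
#'   chain; defaults to the range of the records.
#' @param min_half_width Floor on the half-width, degrees.
#' @param sd_factor Multiplier on the TALOS standard deviation.
#' @return A `dihedral_restraints` data.frame; attribute `"skipped"` lists
#'   skipped (resno, angle, reason) rows.
#' @export
talos_to_dihedrals <- function(records, chain = "A",
                               residue_range = range(records$resno),
                               min_half_width = 20, sd_factor = 1.5) {
  out <- list()
  skipped <- data.frame(resno = integer(0L), angle = character(0L),
                        reason = character(0L), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    if (!rec$usable) next
    if (rec$resno <= residue_range[1L]) {
      skipped <- rbind(skipped, data.frame(
        resno = rec$resno, angle = "phi",
        reason = "no preceding residue for C'(i-1)"))
    } else {
      out[[length(out) + 1L]] <- dihedral_restraint(
        chain, c(rec$resno - 1L, rec$resno, rec$resno, rec$resno),
        c("C", "N", "CA", "C"), target = rec$phi,
        half_width = max(min_half_width, sd_factor * rec$phi_sd),
        angle_name = "phi")
    }
    if (rec$resno >= residue_range[2L]) {
      skipped <- rbind(skipped, data.frame(
        resno = rec$resno, angle = "psi",
        reason = "no following residue for N(i+1)"))
    } else {
      out[[length(out) + 1L]] <- dihedral_restraint(
        chain, c(rec$resno, rec$resno, rec$resno, rec$resno + 1L),
        c("N", "CA", "C", "N"), target = rec$psi,
        half_width = max(min_half_width, sd_factor * rec$psi_sd),
        angle_name = "psi")
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_dihedral_restraints()
  class(res) <- c("dihedral_restraints", "data.frame")
  attr(res, "skipped") <- skipped
  res
}
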