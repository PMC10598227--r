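#' Write a covalent topology as columnar text
#'
#' One record per line: `BOND`/`ANGLE`/`IMPROPER`, the chain/resno/atom
#' identity of each participating atom, the equilibrium value (A or
#' degrees), the force constant, and the ligand flag.
#'
#' @param topology A [covalent_topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  lines <- character(0L)
  fmt_atoms <- function(d, n) {
    do.call(paste, c(lapply(seq_len(n), function(k)
      sprintf("%s %d %s", d[[paste0("chain_", k)]],
              d[[paste0("resno_", k)]], d[[paste0("atom_", k)]])),
      sep = " "))
  }
  if (!is.null(topology$bonds))
    lines <- c(lines, sprintf("BOND %s %.6f %.3f %d",
                              fmt_atoms(topology$bonds, 2L),
                              topology$bonds$r0, topology$bonds$k,
                              as.integer(topology$bonds$ligand)))
  if (!is.null(topology$angles))
    lines <- c(lines, sprintf("ANGLE %s %.6f %.3f %d",
                              fmt_atoms(topology$angles, 3L),
                              topology$angles$theta0, topology$angles$k,
                              as.integer(topology$angles$ligand)))
  if (!is.null(topology$impropers))
    lines <- c(lines, sprintf("IMPROPER %s %.6f %.3f %d",
                              fmt_atoms(topology$impropers, 4L),
                              topology$impropers$phi0, topology$impropers$k,
                              as.integer(topology$impropers$ligand)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a columnar topology file
#'
#' @param path File written by [write_topology()].
#' @return A [covalent_topology()].
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parse_block <- function(tag, n_atoms, value_name) {
    sel <- grep(paste0("^", tag, " "), lines, value = TRUE)
    if (length(sel) == 0L) return(NULL)
    f <- do.call(rbind, strsplit(trimws(sub(paste0("^", tag), "", sel)),
                                 "[[:space:]]+"))
    out <- list()
    for (k in seq_len(n_atoms)) {
      out[[paste0("chain_", k)]] <- f[, 3L * k - 2L]
      out[[paste0("resno_", k)]] <- as.integer(f[, 3L * k - 1L])
      out[[paste0("atom_", k)]] <- f[, 3L * k]
    }
    out[[value_name]] <- as.numeric(f[, 3L * n_atoms + 1L])
    out$k <- as.numeric(f[, 3L * n_atoms + 2L])
    out$ligand <- f[, 3L * n_atoms + 3L] == "1"
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  covalent_topology(parse_block("BOND", 2L, "r0"),
                    parse_block("ANGLE", 3L, "theta0"),
                    parse_block("IMPROPER", 4L, "phi0"))
}

#' Write dihedral restraints as TSV
#'
#' @param dihedrals A `dihedral_restraints` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dihedral_table <- function(dihedrals, path) {
  utils::write.table(as.data.frame(dihedrals), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read dihedral restraints from TSV
#'
#' @param path File written by [write_dihedral_table()].
#' @return A `dihedral_restraints` data.frame.
#' @export
read_dihedral_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(empty_dihedral_restraints())
  class(d) <- c("dihedral_restraints", "data.frame")
  d
}

#' Path to a packaged example data file
#'
#' The package ships two published-table transcriptions as plain text: the
#' intermolecular NOE table of the Bcl-2-xL/35 complex
#' (`bcl2_intermolecular_noe.tsv`) and its restraint-count manifest
#' (`bcl2_restraint_counts.tsv`).
#'
#' @param file File name under `extdata`; `NULL` lists the available
#'   files.
#' @return Full path (or a vector of file names).
#' @export
noetools_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "noetools")))
  path <- system.file("extdata", file, package = "noetools")
  if (!nzchar(path)) stop("no packaged file called '", file, "'")
  path
}
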