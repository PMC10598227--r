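#!/usr/bin/env Rscript
# Optional helper (requires network access): download the deposited
# 20-model ensemble of the Bcl-2-xL/35 complex (PDB 8U27) and run the
# package's ensemble statistics on it — the average pairwise backbone and
# heavy-atom RMSD over residues 10-31 and 47-176. The deposited restraint
# file uses CNS dialects beyond the subset this package parses, so the
# violation analysis is run only if the restraints parse cleanly.
#
# usage: Rscript scripts/fetch_8u27.R [--out results/8u27]

suppressPackageStartupMessages(library(noetools))

args <- commandArgs(trailingOnly = TRUE)
out_dir <- if ("--out" %in% args) args[match("--out", args) + 1L] else
  "results/8u27"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

pdb_path <- file.path(out_dir, "8u27.pdb")
if (!file.exists(pdb_path)) {
  message("downloading 8U27 ...")
  utils::download.file("https://files.rcsb.org/download/8U27.pdb",
                       pdb_path, quiet = TRUE)
}

ens <- read_structure(pdb_path)
message("models: ", length(ens$models))

chain <- unique(ens$models[[1L]]$atoms$chain)[1L]
sel <- atom_selection(chain, rbind(c(10L, 31L), c(47L, 176L)))
tab <- region_rmsd_table(ens, list(`10-31,47-176` = sel))
print(tab, row.names = FALSE)
utils::write.table(tab, file.path(out_dir, "region_rmsd.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

tbl_path <- file.path(out_dir, "8u27_restraints.tbl")
if (!file.exists(tbl_path)) {
  ok <- tryCatch({
    utils::download.file(
      "https://files.rcsb.org/download/8U27.mr", tbl_path, quiet = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) message("restraint download failed; skipping violations")
}
if (file.exists(tbl_path)) {
  set <- tryCatch(parse_distance_table(readLines(tbl_path), "cns_tbl"),
                  error = function(e) {
                    message("deposited restraints use an unsupported ",
                            "dialect: ", conditionMessage(e))
                    NULL
                  })
  if (!is.null(set)) {
    rep <- violation_report(ens, set)
    print(rep)
    write_violation_report(rep, file.path(out_dir, "violations.tsv"))
  }
}
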