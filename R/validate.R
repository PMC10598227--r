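#' Ensemble violation report
#'
#' Evaluates every restraint against every model and summarizes the
#' violations under both ambiguous-averaging conventions (`r6_average` and
#' `r6_sum`) in one pass, alongside the dihedral restraints. Restraints
#' whose selectors cannot be resolved on the ensemble's atom table (naming
#' dialects of deposited restraint files vary) are listed in a skipped
#' section rather than failing.
#'
#' Summary statistics per convention: the per-restraint-per-model
#' violation matrix, per-model mean violation, the mean and standard
#' deviation over the per-model means (the usual "violations (mean and
#' s.d.)" table entry; an alternative over all restraint-by-model cells is
#' also reported), the maximum violation, and counts above the thresholds.
#'
#' @param ensemble An [nmr_ensemble()].
#' @param restraints A [restraint_set()].
#' @param thresholds Named numeric, `distance` (A) and `dihedral`
#'   (degrees) count thresholds.
#' @return Object of class `violation_report`.
#' @export
violation_report <- function(ensemble, restraints,
                             thresholds = c(distance = 0.2, dihedral = 2)) {
  models <- ensemble$models
  ref <- models[[1L]]
  n_m <- length(models)

  dist <- restraints$distance
  skipped <- data.frame(kind = character(0L), index = integer(0L),
                        reason = character(0L), stringsAsFactors = FALSE)
  pair_list <- vector("list", nrow(dist))
  keep <- logical(nrow(dist))
  for (r in seq_len(nrow(dist))) {
    sel <- distance_restraint_selectors(dist[r, ])
    pr <- tryCatch(expand_pair(sel[[1L]], sel[[2L]], ref), error = identity)
    if (inherits(pr, "error")) {
      skipped <- rbind(skipped, data.frame(kind = "distance", index = r,
                                           reason = conditionMessage(pr)))
    } else {
      pair_list[[r]] <- pr
      keep[r] <- TRUE
    }
  }
  kept <- which(keep)
  npairs <- vapply(pair_list[kept], nrow, integer(1L))
  pairs <- do.call(rbind, pair_list[kept])
  rid <- rep.int(seq_along(kept), npairs)

  dmat <- list(r6_average = matrix(0, length(kept), n_m),
               r6_sum = matrix(0, length(kept), n_m))
  if (length(kept) > 0L) {
    lower <- dist$lower[kept]
    upper <- dist$upper[kept]
    for (m in seq_len(n_m)) {
      xyz <- coords(models[[m]])
      d <- sqrt(rowSums((xyz[pairs[, 1L], , drop = FALSE] -
                         xyz[pairs[, 2L], , drop = FALSE])^2))
      S <- as.numeric(rowsum(d^(-6), rid))
      for (method in names(dmat)) {
        Sm <- if (method == "r6_average") S / npairs else S
        deff <- Sm^(-1 / 6)
        dmat[[method]][, m] <- pmax(0, deff - upper, lower - deff)
      }
    }
  }

  dihr <- restraints$dihedral
  quad_ok <- logical(nrow(dihr))
  quads <- matrix(0L, nrow(dihr), 4L)
  for (r in seq_len(nrow(dihr))) {
    q <- tryCatch(dihedral_restraint_atoms(dihr[r, ], ref), error = identity)
    if (inherits(q, "error")) {
      skipped <- rbind(skipped, data.frame(kind = "dihedral", index = r,
                                           reason = conditionMessage(q)))
    } else {
      quads[r, ] <- q
      quad_ok[r] <- TRUE
    }
  }
  dk <- which(quad_ok)
  dihmat <- matrix(0, length(dk), n_m)
  if (length(dk) > 0L) {
    for (m in seq_len(n_m)) {
      obs <- torsion_angles(coords(models[[m]]), quads[dk, , drop = FALSE])
      dihmat[, m] <- pmax(0, abs(wrap_angle(obs - dihr$target[dk])) -
                             dihr$half_width[dk])
    }
  }

  summarize <- function(mat, thr) {
    if (length(mat) == 0L) {
      return(list(per_model_mean = rep(0, n_m), mean = 0, sd = 0,
                  cell_mean = 0, cell_sd = 0, max = 0, n_above = 0L,
                  threshold = thr))
    }
    pmm <- colMeans(mat)
    list(per_model_mean = pmm, mean = mean(pmm),
         sd = if (n_m > 1L) stats::sd(pmm) else 0,
         cell_mean = mean(mat), cell_sd = stats::sd(as.numeric(mat)),
         max = max(mat), n_above = sum(mat > thr), threshold = thr)
  }

  structure(list(
    distance = list(
      r6_average = c(list(matrix = dmat$r6_average),
                     summarize(dmat$r6_average, thresholds[["distance"]])),
      r6_sum = c(list(matrix = dmat$r6_sum),
                 summarize(dmat$r6_sum, thresholds[["distance"]])),
      restraint_index = kept),
    dihedral = c(list(matrix = dihmat, restraint_index = dk),
                 summarize(dihmat, thresholds[["dihedral"]])),
    skipped = skipped, n_models = n_m, thresholds = thresholds),
    class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("Violation report over %d models\n", x$n_models))
  for (method in c("r6_average", "r6_sum")) {
    s <- x$distance[[method]]
    cat(sprintf(
      "  distance (%s): mean %.4g +/- %.4g A, max %.4g A, %d above %.2g A\n",
      method, s$mean, s$sd, s$max, s$n_above, s$threshold))
  }
  s <- x$dihedral
  cat(sprintf(
    "  dihedral: mean %.4g +/- %.4g deg, max %.4g deg, %d above %.2g deg\n",
    s$mean, s$sd, s$max, s$n_above, s$threshold))
  if (nrow(x$skipped) > 0L)
    cat("  skipped restraints:", nrow(x$skipped), "\n")
  invisible(x)
}

#' Write a violation report as TSV
#'
#' One row per convention/dihedral block with the summary statistics.
#'
#' @param report A [violation_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_violation_report <- function(report, path) {
  rows <- lapply(c("r6_average", "r6_sum"), function(m) {
    s <- report$distance[[m]]
    data.frame(block = paste0("distance_", m), mean = s$mean, sd = s$sd,
               max = s$max, n_above = s$n_above, threshold = s$threshold)
  })
  s <- report$dihedral
  rows <- c(rows, list(data.frame(block = "dihedral", mean = s$mean,
                                  sd = s$sd, max = s$max,
                                  n_above = s$n_above,
                                  threshold = s$threshold)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Region-wise average pairwise RMSD table
#'
#' Mean pairwise RMSD (each model pair independently superposed) per named
#' selection, for both the selection's backbone atoms and all heavy atoms
#' of the selected residues.
#'
#' @param ensemble An [nmr_ensemble()] with at least two models.
#' @param selections Named list of [atom_selection()]s (their atom set is
#'   overridden by `backbone`/`heavy` per column).
#' @return data.frame with columns `name`, `backbone_rmsd`, `heavy_rmsd`
#'   (Angstrom).
#' @export
region_rmsd_table <- function(ensemble, selections) {
  if (length(ensemble$models) < 2L) stop("at least two models are required")
  if (is.null(names(selections)) || any(!nzchar(names(selections))))
    stop("selections must be named")
  out <- lapply(names(selections), function(nm) {
    sel <- selections[[nm]]
    bb <- atom_selection(sel$chain, sel$ranges, "backbone")
    hv <- atom_selection(sel$chain, sel$ranges, "heavy")
    data.frame(name = nm,
               backbone_rmsd = mean_pairwise_rmsd(ensemble, bb),
               heavy_rmsd = mean_pairwise_rmsd(ensemble, hv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Residues in contact with a ligand
#'
#' All residues (outside the ligand selection) with any heavy atom within
#' `cutoff` of any ligand heavy atom — the common van der Waals contact
#' convention.
#'
#' @param structure An [nmr_structure()].
#' @param ligand_selection An [atom_selection()] covering the ligand.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return Object of class `contact_site`: data.frame (`chain`, `resno`,
#'   `resname`) with attribute `cutoff`.
#' @export
contact_residues <- function(structure, ligand_selection, cutoff = 4.5) {
  at <- structure$atoms
  lig <- resolve_selection(
    atom_selection(ligand_selection$chain, ligand_selection$ranges, "all"),
    structure)
  lig <- lig[!is_hydrogen_name(at$atname[lig])]
  if (length(lig) == 0L) stop("ligand selection matches no heavy atoms")
  heavy <- which(!is_hydrogen_name(at$atname))
  prot <- setdiff(heavy, lig)
  xyz <- coords(structure)
  close_res <- character(0L)
  if (length(prot) > 0L) {
    d2 <- outer(rowSums(xyz[prot, , drop = FALSE]^2),
                rowSums(xyz[lig, , drop = FALSE]^2), "+") -
      2 * xyz[prot, , drop = FALSE] %*% t(xyz[lig, , drop = FALSE])
    hit <- prot[apply(d2 <= cutoff^2 + 1e-12, 1L, any)]
    close_res <- unique(paste(at$chain[hit], at$resno[hit], at$resname[hit]))
  }
  out <- if (length(close_res) > 0L) {
    parts <- strsplit(close_res, " ", fixed = TRUE)
    data.frame(chain = vapply(parts, `[[`, "", 1L),
               resno = as.integer(vapply(parts, `[[`, "", 2L)),
               resname = vapply(parts, `[[`, "", 3L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = character(0L), resno = integer(0L),
               resname = character(0L), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_site", "data.frame")
  out
}

#' Overlap between two contact sites
#'
#' Jaccard index of the residue sets plus the fraction of the first site's
#' residues not shared with the second — a quantitative handle on "how much
#' of site A is unique".
#'
#' @param site_a,site_b [contact_residues()] results on the same
#'   structure/numbering.
#' @return List with `jaccard` (in `[0, 1]`) and `fraction_a_unique`.
#' @export
site_overlap <- function(site_a, site_b) {
  ka <- paste(site_a$chain, site_a$resno)
  kb <- paste(site_b$chain, site_b$resno)
  if (length(ka) == 0L && length(kb) == 0L)
    stop("both contact sites are empty")
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  list(jaccard = inter / uni,
       fraction_a_unique = if (length(ka) == 0L) 0 else
         length(setdiff(ka, kb)) / length(ka))
}
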