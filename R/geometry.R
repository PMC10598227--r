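#' Effective distance of an ambiguous proton pair list
#'
#' Collapses the distances of all proton pairs matched by a pseudoatom
#' restraint into one effective distance, under either of the two
#' conventions used for ambiguous NOE restraints:
#' \describe{
#'   \item{`r6_average`}{\eqn{(\mathrm{mean}_p\, d_p^{-6})^{-1/6}}}
#'   \item{`r6_sum`}{\eqn{(\sum_p d_p^{-6})^{-1/6}}}
#' }
#' For a single pair both equal the plain distance; for \eqn{N} pairs the two
#' are related exactly by \eqn{d_{avg} = N^{1/6} d_{sum}}, so the summed form
#' is always the shorter (more conservative against an upper bound).
#'
#' @param pairs Two-column integer matrix of atom-index pairs
#'   (from [expand_pair()]).
#' @param structure An [nmr_structure()].
#' @param method `"r6_average"` or `"r6_sum"`.
#' @return Effective distance in Angstrom.
#' @examples
#' s <- nmr_structure(data.frame(chain = "A", resno = 1, resname = "GLY",
#'   atname = c("H1", "H2", "H3"), x = c(0, 2, 4), y = 0, z = 0))
#' effective_distance(cbind(1, 2:3), s, "r6_average")
#' @export
effective_distance <- function(pairs, structure,
                               method = c("r6_average", "r6_sum")) {
  method <- match.arg(method)
  pairs <- rbind(pairs)
  if (nrow(pairs) < 1L) stop("at least one pair is required")
  xyz <- coords(structure)
  d <- sqrt(rowSums((xyz[pairs[, 1L], , drop = FALSE] -
                     xyz[pairs[, 2L], , drop = FALSE])^2))
  r6_combine(d, method)
}

r6_combine <- function(d, method) {
  if (any(d == 0)) stop("coincident atoms (zero distance) in pair list")
  s <- sum(d^(-6))
  if (method == "r6_average") s <- s / length(d)
  s^(-1 / 6)
}

#' Distance-restraint violation
#'
#' The amount by which the effective distance falls outside the restraint's
#' bounds: `max(0, d_eff - upper, lower - d_eff)`, in Angstrom.
#'
#' @param restraint One distance restraint (one-row slice of the
#'   `distance` table of a [restraint_set()]).
#' @param structure An [nmr_structure()].
#' @param method Averaging convention, see [effective_distance()].
#' @return Non-negative violation in Angstrom.
#' @export
distance_violation <- function(restraint, structure,
                               method = c("r6_average", "r6_sum")) {
  method <- match.arg(method)
  sel <- distance_restraint_selectors(restraint)
  d <- effective_distance(expand_pair(sel[[1L]], sel[[2L]], structure),
                          structure, method)
  max(0, d - restraint$upper[1L], restraint$lower[1L] - d)
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Signed torsions (degrees, IUPAC convention) for quadruples of row indices
# into xyz; quads is an n x 4 integer matrix.
torsion_angles <- function(xyz, quads) {
  quads <- rbind(quads)
  b1 <- xyz[quads[, 2L], , drop = FALSE] - xyz[quads[, 1L], , drop = FALSE]
  b2 <- xyz[quads[, 3L], , drop = FALSE] - xyz[quads[, 2L], , drop = FALSE]
  b3 <- xyz[quads[, 4L], , drop = FALSE] - xyz[quads[, 3L], , drop = FALSE]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross3(n1, n2) * b2) / nb2
  deg <- atan2(y, x) * 180 / pi
  # map -180 to +180 so angles live in (-180, 180]
  ifelse(deg <= -180, deg + 360, deg)
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion with the IUPAC convention (clockwise positive
#' looking from the second to the third point), in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)) # cis, 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  xyz <- rbind(p1, p2, p3, p4)
  b1 <- xyz[2L, ] - xyz[1L, ]
  b2 <- xyz[3L, ] - xyz[2L, ]
  b3 <- xyz[4L, ] - xyz[3L, ]
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("three consecutive points are collinear")
  unname(torsion_angles(xyz, matrix(1:4, nrow = 1L)))
}

#' Wrap angles into (-180, 180]
#'
#' @param deg Angles in degrees.
#' @return Equivalent angles in (-180, 180].
#' @export
wrap_angle <- function(deg) {
  w <- deg - 360 * round(deg / 360)
  ifelse(w <= -180, w + 360, w)
}

#' Dihedral-restraint violation
#'
#' `max(0, |wrap(observed - target)| - half_width)` in degrees, where `wrap`
#' maps into (-180, 180]; invariant under full-turn shifts of the observed
#' angle.
#'
#' @param restraint One dihedral restraint (one-row slice of the `dihedral`
#'   table of a [restraint_set()]).
#' @param structure An [nmr_structure()].
#' @return Non-negative violation in degrees.
#' @export
dihedral_violation <- function(restraint, structure) {
  idx <- dihedral_restraint_atoms(restraint, structure)
  obs <- torsion_angles(coords(structure), matrix(idx, nrow = 1L))
  max(0, abs(wrap_angle(obs - restraint$target[1L])) -
         restraint$half_width[1L])
}

#' Chiral center descriptor
#'
#' A tetrahedral center plus its four substituents in caller-supplied
#' priority order (highest first). No CIP priority inference is performed;
#' the labels returned by [chirality_sign()] are defined purely by the
#' documented triple-product convention on this order.
#'
#' @param center [atom_selector()] for the central atom.
#' @param substituents List of four [atom_selector()]s, highest priority
#'   first.
#' @return An object of class `chiral_center`.
#' @export
chiral_center <- function(center, substituents) {
  stopifnot(length(substituents) == 4L)
  structure(list(center = center, substituents = substituents),
            class = "chiral_center")
}

resolve_single_atom <- function(selector, structure) {
  idx <- match_atoms(selector, structure)
  if (length(idx) != 1L)
    stop("selector must resolve to exactly one atom: ", format(selector))
  idx
}

#' Handedness of a tetrahedral center
#'
#' Computes the signed volume \eqn{(r_1-r_4)\cdot[(r_2-r_4)\times(r_3-r_4)]}
#' with substituents taken in the supplied priority order. By convention a
#' negative triple product is labelled `"R_like"` and a positive one
#' `"S_like"`. The label is invariant under rigid motion and flips under
#' reflection.
#'
#' @param center A [chiral_center()].
#' @param structure An [nmr_structure()].
#' @param tolerance Absolute triple-product volume below which the
#'   arrangement is declared planar/indeterminate.
#' @return `"R_like"` or `"S_like"`.
#' @export
chirality_sign <- function(center, structure, tolerance = 1e-4) {
  xyz <- coords(structure)
  idx <- vapply(c(list(center$center), center$substituents),
                resolve_single_atom, integer(1L), structure = structure)
  if (anyDuplicated(idx)) stop("chiral-center selectors must be distinct atoms")
  r <- xyz[idx[2:5], , drop = FALSE]
  v1 <- r[1L, ] - r[4L, ]
  v2 <- r[2L, ] - r[4L, ]
  v3 <- r[3L, ] - r[4L, ]
  t <- sum(v1 * c(v2[2L] * v3[3L] - v2[3L] * v3[2L],
                  v2[3L] * v3[1L] - v2[1L] * v3[3L],
                  v2[1L] * v3[2L] - v2[2L] * v3[1L]))
  if (abs(t) < tolerance)
    stop("planar/indeterminate center (|triple product| = ",
         signif(abs(t), 3), ")")
  if (t < 0) "R_like" else "S_like"
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping the selected atoms of
#' `mobile` onto `reference`, with the post-fit RMSD. The returned rotation
#' always has determinant +1 (no reflection).
#'
#' @param mobile,reference [nmr_structure()]s sharing the selection's atoms.
#' @param selection An [atom_selection()], or `NULL` to use all atoms.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `mobile_fitted` (the transformed mobile structure).
#'   The fitted mobile coordinates are `xyz %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) {
    im <- seq_len(nrow(mobile$atoms))
    ir <- seq_len(nrow(reference$atoms))
  } else {
    im <- resolve_selection(selection, mobile)
    ir <- resolve_selection(selection, reference)
  }
  idm <- atom_identity(mobile)[im]
  idr <- atom_identity(reference)[ir]
  if (!identical(idm, idr)) {
    k <- which(idm != idr | is.na(idm) | is.na(idr))[1L]
    if (is.na(k)) k <- min(length(idm), length(idr)) + 1L
    stop("selection resolves to different atom lists; first disagreement ",
         "at position ", k, ": '", idm[k], "' vs '", idr[k], "'")
  }
  P <- coords(mobile)[im, , drop = FALSE]
  Q <- coords(reference)[ir, , drop = FALSE]
  if (nrow(P) < 2L) stop("at least 2 atoms are required for superposition")
  # (3+ non-collinear atoms are needed for the rotation itself to be
  # unique; the rmsd is well defined from 2 atoms on)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  s <- svd(crossprod(Pc, Qc))        # H = t(Pc) Qc = U D t(V)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Qc)^2)))
  translation <- cq - as.numeric(R %*% cp)
  all_fit <- sweep(coords(mobile) %*% t(R), 2L, translation, "+")
  list(rotation = R, translation = translation, rmsd = rmsd,
       mobile_fitted = set_coords(mobile, all_fit))
}

#' Average pairwise ensemble RMSD
#'
#' Mean of the post-superposition RMSD over all unordered model pairs, each
#' pair independently fitted on the selection — the "average pairwise
#' r.m.s. deviation" convention for NMR ensembles.
#'
#' @param ensemble An [nmr_ensemble()] with at least two models.
#' @param selection An [atom_selection()], or `NULL` for all atoms.
#' @return Mean pairwise RMSD in Angstrom.
#' @export
mean_pairwise_rmsd <- function(ensemble, selection = NULL) {
  n <- length(ensemble$models)
  if (n < 2L) stop("at least two models are required")
  tot <- 0
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      tot <- tot + superpose(ensemble$models[[a]], ensemble$models[[b]],
                             selection)$rmsd
    }
  }
  tot / (n * (n - 1L) / 2)
}
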