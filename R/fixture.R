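## Ideal covalent geometry used by the generator (lengths A, angles deg)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_N_H  <- 1.020
BOND_CA_CB <- 1.530
BOND_C_H  <- 1.090
ANGLE_C_N_CA <- 121.7
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_CA_C_O <- 120.8
ANGLE_N_CA_CB <- 110.5
ANGLE_X_C_H <- 109.5

METHYL_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "THR", "MET")

## Ligand improper force constant: after the 0.2 ligand scaling this must
## still dominate the restraint forces, so the toy ligand behaves as the
## rigid chiral body the screen assumes (no hand flip during minimization).
LIGAND_K_IMPROPER <- 2500

unit3 <- function(v) v / sqrt(sum(v^2))

# place atom D bonded to C given the A-B-C frame, with bond length |CD|,
# angle B-C-D and torsion A-B-C-D (natural extension reference frame)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(c(
    (b - a)[2L] * bc[3L] - (b - a)[3L] * bc[2L],
    (b - a)[3L] * bc[1L] - (b - a)[1L] * bc[3L],
    (b - a)[1L] * bc[2L] - (b - a)[2L] * bc[1L]))
  m <- c(n[2L] * bc[3L] - n[3L] * bc[2L],
         n[3L] * bc[1L] - n[1L] * bc[3L],
         n[1L] * bc[2L] - n[2L] * bc[1L])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

#' Build an ideal helical protein fragment
#'
#' Backbone (N, H, CA, C, O) chained by torsions at the requested phi/psi
#' with trans peptide bonds and ideal bond lengths/angles; side chains are
#' reduced to a C-beta, plus a pseudo-methyl (HB1/HB2/HB3 on C-beta) for
#' methyl-bearing residue types (`r toString(METHYL_RESIDUES)`). Glycine
#' gets no C-beta; the N-terminal residue carries no amide proton. The
#' built phi/psi reproduce the requested values to well under 0.5 degrees.
#'
#' @param sequence One-letter sequence (>= 4 residues).
#' @param phi,psi Backbone torsions in degrees (defaults: ideal
#'   alpha-helix, -57/-47).
#' @param chain Chain identifier.
#' @return An [nmr_structure()].
#' @examples
#' hel <- make_ideal_helix("AAKLLEAMVA")
#' @export
make_ideal_helix <- function(sequence, phi = -57, psi = -47, chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  if (length(letters1) < 4L)
    stop("sequence must have at least 4 residues")
  res3 <- AA1TO3[letters1]
  if (anyNA(res3))
    stop("unknown residue letter: ", letters1[is.na(res3)][1L])
  n_res <- length(res3)

  rows <- list()
  add <- function(resno, resname, atname, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resname = resname, atname = atname,
      x = xyz[1L], y = xyz[2L], z = xyz[3L], stringsAsFactors = FALSE)
  }

  dummy <- c(0, -1, 0)
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  C <- place_atom(dummy, N, CA, BOND_CA_C, ANGLE_N_CA_C, phi)
  prevC <- list(dummy)  # "C'" frame atom preceding residue 1
  pos <- list()
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N <- place_atom(pos[[i - 1L]]$N, pos[[i - 1L]]$CA, pos[[i - 1L]]$C,
                      BOND_C_N, ANGLE_CA_C_N, psi)
      CA <- place_atom(pos[[i - 1L]]$CA, pos[[i - 1L]]$C, N,
                       BOND_N_CA, ANGLE_C_N_CA, 180)
      C <- place_atom(pos[[i - 1L]]$C, N, CA, BOND_CA_C, ANGLE_N_CA_C, phi)
      prevC[[i]] <- pos[[i - 1L]]$C
    }
    pos[[i]] <- list(N = N, CA = CA, C = C)
  }
  for (i in seq_len(n_res)) {
    p <- pos[[i]]
    add(i, res3[i], "N", p$N)
    if (i > 1L) {
      hdir <- -unit3(unit3(prevC[[i]] - p$N) + unit3(p$CA - p$N))
      add(i, res3[i], "H", p$N + BOND_N_H * hdir)
    }
    add(i, res3[i], "CA", p$CA)
    add(i, res3[i], "C", p$C)
    add(i, res3[i], "O",
        place_atom(p$N, p$CA, p$C, BOND_C_O, ANGLE_CA_C_O,
                   wrap_angle(psi + 180)))
    if (res3[i] != "GLY") {
      CB <- place_atom(prevC[[i]], p$N, p$CA, BOND_CA_CB, ANGLE_N_CA_CB,
                       wrap_angle(phi + 122.5))
      add(i, res3[i], "CB", CB)
      if (res3[i] %in% METHYL_RESIDUES) {
        for (k in 1:3)
          add(i, res3[i], paste0("HB", k),
              place_atom(p$N, p$CA, CB, BOND_C_H, ANGLE_X_C_H,
                         60 + 120 * (k - 1L)))
      }
    }
  }
  nmr_structure(do.call(rbind, rows))
}

TETRA <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
  sqrt(3)

#' Build a rigid chiral toy ligand
#'
#' A small organic fragment (8 heavy atoms plus hydrogens) with one
#' tetrahedral stereocenter C1 carrying O1 (hydroxyl), C2 (methyl, protons
#' HM1-3), C3 (a short substituted chain: H31, methyl C4 with HK1-3, and an
#' amide-like N1-C5=O2 arm with HN1) and H1. The R and S builds are exact
#' mirror images; the returned topology carries improper terms measured
#' from the built geometry, so minimization enforces the requested hand.
#'
#' @param handedness `"R"` or `"S"` — the [chirality_sign()] of the built
#'   fragment under the returned chiral center (priorities O1 > C3 > C2 >
#'   H1).
#' @param chain,resno,resname Identity given to the ligand atoms.
#' @return List: `structure` ([nmr_structure()]), `topology`
#'   ([covalent_topology()]), `center` ([chiral_center()]), `bonds`
#'   (index-free bond table used for topology enumeration).
#' @export
make_toy_ligand <- function(handedness = c("S", "R"), chain = "L",
                            resno = 1L, resname = "LIG") {
  handedness <- match.arg(handedness)
  C1 <- c(0, 0, 0)
  O1 <- C1 + 1.43 * TETRA[1L, ]
  C2 <- C1 + 1.53 * TETRA[2L, ]
  C3 <- C1 + 1.53 * TETRA[3L, ]
  H1 <- C1 + 1.09 * TETRA[4L, ]
  HO1 <- place_atom(C2, C1, O1, 0.97, 107, 180)
  HM <- lapply(1:3, function(k)
    place_atom(O1, C1, C2, BOND_C_H, ANGLE_X_C_H, 60 + 120 * (k - 1L)))
  C4 <- place_atom(O1, C1, C3, 1.53, ANGLE_X_C_H, 180)
  N1 <- place_atom(O1, C1, C3, 1.47, ANGLE_X_C_H, 60)
  H31 <- place_atom(O1, C1, C3, BOND_C_H, ANGLE_X_C_H, -60)
  HK <- lapply(1:3, function(k)
    place_atom(C1, C3, C4, BOND_C_H, ANGLE_X_C_H, 60 + 120 * (k - 1L)))
  C5 <- place_atom(C1, C3, N1, 1.35, 120, 180)
  O2 <- place_atom(C3, N1, C5, 1.23, 121, 0)
  HN1 <- place_atom(C3, N1, C5, BOND_N_H, 118, 180)

  names_xyz <- list(C1 = C1, O1 = O1, HO1 = HO1, C2 = C2,
                    HM1 = HM[[1L]], HM2 = HM[[2L]], HM3 = HM[[3L]],
                    C3 = C3, H31 = H31, C4 = C4,
                    HK1 = HK[[1L]], HK2 = HK[[2L]], HK3 = HK[[3L]],
                    N1 = N1, HN1 = HN1, C5 = C5, O2 = O2, H1 = H1)
  atoms <- data.frame(chain = chain, resno = resno, resname = resname,
                      atname = names(names_xyz),
                      do.call(rbind, lapply(names_xyz, function(p)
                        data.frame(x = p[1L], y = p[2L], z = p[3L]))),
                      het = TRUE, stringsAsFactors = FALSE)
  s <- nmr_structure(atoms)

  center <- chiral_center(
    atom_selector(chain, resno, "C1"),
    list(atom_selector(chain, resno, "O1"), atom_selector(chain, resno, "C3"),
         atom_selector(chain, resno, "C2"), atom_selector(chain, resno, "H1")))
  if (chirality_sign(center, s) != paste0(handedness, "_like")) {
    xyz <- coords(s)
    xyz[, 3L] <- -xyz[, 3L]
    s <- set_coords(s, xyz)
  }

  bonds <- rbind(
    c("C1", "O1"), c("O1", "HO1"), c("C1", "C2"),
    c("C2", "HM1"), c("C2", "HM2"), c("C2", "HM3"),
    c("C1", "C3"), c("C3", "H31"), c("C3", "C4"),
    c("C4", "HK1"), c("C4", "HK2"), c("C4", "HK3"),
    c("C3", "N1"), c("N1", "HN1"), c("N1", "C5"), c("C5", "O2"),
    c("C1", "H1"))
  # proper torsions that rigidify the single-bond rotations of the fragment
  extra <- rbind(c("O1", "C1", "C3", "C4"), c("O1", "C1", "C2", "HM1"),
                 c("C1", "C3", "C4", "HK1"), c("C1", "C3", "N1", "C5"),
                 c("C3", "N1", "C5", "O2"), c("C2", "C1", "O1", "HO1"))
  topo <- measure_topology(s, bond_table(s, bonds), extra_impropers = extra,
                           k_improper = LIGAND_K_IMPROPER)
  list(structure = s, topology = topo, center = center, bonds = bonds)
}

bond_table <- function(structure, name_pairs) {
  at <- structure$atoms
  data.frame(chain_1 = at$chain[1L], resno_1 = at$resno[1L],
             atom_1 = name_pairs[, 1L],
             chain_2 = at$chain[1L], resno_2 = at$resno[1L],
             atom_2 = name_pairs[, 2L], stringsAsFactors = FALSE)
}

protein_bond_table <- function(structure) {
  at <- structure$atoms
  out <- list()
  push <- function(c1, r1, a1, c2, r2, a2) {
    out[[length(out) + 1L]] <<- data.frame(
      chain_1 = c1, resno_1 = r1, atom_1 = a1,
      chain_2 = c2, resno_2 = r2, atom_2 = a2, stringsAsFactors = FALSE)
  }
  prot <- at[!at$het, ]
  for (ch in unique(prot$chain)) {
    res <- sort(unique(prot$resno[prot$chain == ch]))
    for (r in res) {
      names_r <- prot$atname[prot$chain == ch & prot$resno == r]
      push(ch, r, "N", ch, r, "CA")
      push(ch, r, "CA", ch, r, "C")
      push(ch, r, "C", ch, r, "O")
      if ("H" %in% names_r) push(ch, r, "N", ch, r, "H")
      if ("CB" %in% names_r) push(ch, r, "CA", ch, r, "CB")
      for (hb in grep("^HB[123]$", names_r, value = TRUE))
        push(ch, r, "CB", ch, r, hb)
      if ((r + 1L) %in% res) push(ch, r, "C", ch, r + 1L, "N")
    }
  }
  do.call(rbind, out)
}

#' Measure a harmonic topology from a structure
#'
#' Enumerates angle terms (every neighbour pair at every bonded centre) and
#' improper terms (one torsion per centre with three or more neighbours,
#' which encodes local planarity or chirality) from a bond list, and sets
#' every equilibrium value to the geometry measured in `structure`, so the
#' input structure is the exact minimum of the covalent energy.
#'
#' @param structure An [nmr_structure()] providing the reference geometry.
#' @param bonds data.frame of bonded atom pairs (identity columns
#'   `chain_1, resno_1, atom_1, chain_2, resno_2, atom_2`).
#' @param k_bond,k_angle,k_improper Force constants.
#' @param extra_impropers Optional matrix/data.frame of extra torsion
#'   quadruples (atom names, single-residue fragments) or identity-column
#'   data.frame rows for inter-residue torsions.
#' @param ligand_chain Chain whose terms are flagged `ligand` (scaled by
#'   the energy model's `ligand_scale`).
#' @return A [covalent_topology()].
#' @export
measure_topology <- function(structure, bonds, k_bond = 1000, k_angle = 100,
                             k_improper = 50, extra_impropers = NULL,
                             ligand_chain = "L") {
  lookup <- atom_index_lookup(structure)
  xyz <- coords(structure)
  at <- structure$atoms
  key <- function(cc, rr, aa) paste(cc, rr, aa)
  i1 <- lookup[key(bonds$chain_1, bonds$resno_1, bonds$atom_1)]
  i2 <- lookup[key(bonds$chain_2, bonds$resno_2, bonds$atom_2)]
  if (anyNA(i1) || anyNA(i2))
    stop("bond references a missing atom")
  is_lig <- function(idx) at$chain[idx] == ligand_chain
  ident <- function(idx, k) {
    d <- data.frame(at$chain[idx], at$resno[idx], at$atname[idx],
                    stringsAsFactors = FALSE)
    names(d) <- paste0(c("chain_", "resno_", "atom_"), k)
    d
  }
  dist_of <- function(a, b) sqrt(rowSums((xyz[a, , drop = FALSE] -
                                          xyz[b, , drop = FALSE])^2))
  bonds_df <- cbind(ident(i1, 1L), ident(i2, 2L),
                    r0 = dist_of(i1, i2), k = k_bond,
                    ligand = is_lig(i1) | is_lig(i2))

  nbrs <- split(c(i2, i1), c(i1, i2))
  ang <- list()
  imp <- list()
  for (ctr_chr in names(nbrs)) {
    ctr <- as.integer(ctr_chr)
    nb <- sort(unique(nbrs[[ctr_chr]]))
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      for (cc in seq_len(ncol(cmb)))
        ang[[length(ang) + 1L]] <- c(cmb[1L, cc], ctr, cmb[2L, cc])
    }
    if (length(nb) >= 3L)
      imp[[length(imp) + 1L]] <- c(nb[1L], ctr, nb[2L], nb[3L])
    # a second improper so every substituent of a tetrahedral centre is
    # chirality-constrained (a lone improper leaves the fourth neighbour
    # free to flip through the plane of the other three)
    if (length(nb) >= 4L)
      imp[[length(imp) + 1L]] <- c(nb[2L], ctr, nb[3L], nb[4L])
  }
  amat <- do.call(rbind, ang)
  angle_of <- function(a, b, c) {
    u <- xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE]
    v <- xyz[c, , drop = FALSE] - xyz[b, , drop = FALSE]
    acos(pmin(1, pmax(-1, rowSums(u * v) /
                        (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))))) *
      180 / pi
  }
  angles_df <- cbind(ident(amat[, 1L], 1L), ident(amat[, 2L], 2L),
                     ident(amat[, 3L], 3L),
                     theta0 = angle_of(amat[, 1L], amat[, 2L], amat[, 3L]),
                     k = k_angle, ligand = is_lig(amat[, 2L]))

  imat <- do.call(rbind, imp)
  if (!is.null(extra_impropers)) {
    if (is.matrix(extra_impropers)) {
      ch <- at$chain[i1[1L]]
      rn <- at$resno[i1[1L]]
      eidx <- apply(extra_impropers, c(1L, 2L), function(a)
        lookup[key(ch, rn, a)])
    } else {
      eidx <- sapply(1:4, function(k)
        lookup[key(extra_impropers[[paste0("chain_", k)]],
                   extra_impropers[[paste0("resno_", k)]],
                   extra_impropers[[paste0("atom_", k)]])])
    }
    storage.mode(eidx) <- "integer"
    if (anyNA(eidx)) stop("extra improper references a missing atom")
    imat <- rbind(imat, eidx)
  }
  impropers_df <- NULL
  if (!is.null(imat) && nrow(imat) > 0L) {
    phi0 <- torsion_angles(xyz, imat)
    impropers_df <- cbind(ident(imat[, 1L], 1L), ident(imat[, 2L], 2L),
                          ident(imat[, 3L], 3L), ident(imat[, 4L], 4L),
                          phi0 = phi0, k = k_improper,
                          ligand = is_lig(imat[, 2L]))
  }
  covalent_topology(bonds_df, angles_df, impropers_df)
}

# trans-peptide (omega) torsion terms, which neighbour-centred impropers
# cannot constrain
omega_impropers <- function(structure, ligand_chain = "L") {
  at <- structure$atoms
  prot <- at[!at$het & at$chain != ligand_chain, ]
  out <- list()
  for (ch in unique(prot$chain)) {
    res <- sort(unique(prot$resno[prot$chain == ch]))
    for (r in res[-length(res)]) {
      if (!(r + 1L) %in% res) next
      out[[length(out) + 1L]] <- data.frame(
        chain_1 = ch, resno_1 = r, atom_1 = "CA",
        chain_2 = ch, resno_2 = r, atom_2 = "C",
        chain_3 = ch, resno_3 = r + 1L, atom_3 = "N",
        chain_4 = ch, resno_4 = r + 1L, atom_4 = "CA",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

proton_groups <- function(structure) {
  at <- structure$atoms
  h <- which(is_hydrogen_name(at$atname))
  stem <- sub("[0-9]$", "", at$atname[h])
  gkey <- paste(at$chain[h], at$resno[h], stem)
  split_idx <- split(h, gkey)
  lapply(split_idx, function(idx) {
    pattern <- if (length(idx) > 1L) {
      paste0(sub("[0-9]$", "", at$atname[idx[1L]]), "*")
    } else {
      at$atname[idx]
    }
    list(idx = idx, chain = at$chain[idx[1L]], resno = at$resno[idx[1L]],
         resname = at$resname[idx[1L]], pattern = pattern)
  })
}

#' Derive a restraint set from true coordinates
#'
#' The generative rule reuses the experimental intensity-class table: every
#' proton-group pair (intermolecular, plus intramolecular protein pairs;
#' methyl protons are collapsed to trailing-wildcard pseudoatoms and
#' evaluated by r^-6 averaging) whose r^-6-averaged true distance is at
#' most `cutoff` becomes an NOE restraint of the tightest class whose
#' upper bound covers that distance (plus an optional non-negative noise
#' widening). Pairs whose r^-6-summed distance falls below the universal
#' 1.8 A lower bound (geminal/vicinal contacts) are not restrained, so the
#' truth satisfies every derived restraint under both conventions.
#' Helical i -> i+4 hydrogen bonds contribute paired H/O + N/O restraints,
#' and every interior residue contributes phi/psi restraints centred on
#' the true angles with a 20-degree half-width.
#'
#' @param truth An [nmr_structure()] of protein + docked ligand.
#' @param cutoff Distance cutoff in A (must not exceed 6.0, the widest
#'   class).
#' @param seed RNG seed for the noise draws.
#' @param noise Standard deviation (A) of the half-normal widening added
#'   to the class-assignment distance; 0 disables noise. Noise can only
#'   widen bounds, never create violations of the truth.
#' @param ligand_chain Ligand chain identifier.
#' @return A [restraint_set()].
#' @export
derive_restraints <- function(truth, cutoff = 5.0, seed = 0L, noise = 0,
                              ligand_chain = "L") {
  if (cutoff > 6.0)
    stop("cutoff exceeds the widest intensity class (6.0 A)")
  groups <- proton_groups(truth)
  xyz <- coords(truth)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  ng <- length(groups)
  rows <- list()
  for (a in seq_len(ng - 1L)) {
    ga <- groups[[a]]
    for (b in seq.int(a + 1L, ng)) {
      gb <- groups[[b]]
      a_lig <- ga$chain == ligand_chain
      b_lig <- gb$chain == ligand_chain
      if (a_lig && b_lig) next
      dv <- outer(rowSums(xyz[ga$idx, , drop = FALSE]^2),
                  rowSums(xyz[gb$idx, , drop = FALSE]^2), "+") -
        2 * xyz[ga$idx, , drop = FALSE] %*% t(xyz[gb$idx, , drop = FALSE])
      d <- sqrt(pmax(as.numeric(dv), 0))
      S <- sum(d^(-6))
      d_avg <- (S / length(d))^(-1 / 6)
      if (d_avg > cutoff) next
      d_sum <- S^(-1 / 6)
      if (d_sum < NOE_LOWER_BOUND) next
      eps <- if (noise > 0) abs(stats::rnorm(1L, 0, noise)) else 0
      cls <- intensity_for_distance(min(d_avg + eps, 6.0))
      rows[[length(rows) + 1L]] <- distance_restraint(
        ga$chain, ga$resno, ga$pattern, gb$chain, gb$resno, gb$pattern,
        intensity = cls, resname_i = ga$resname, resname_j = gb$resname)
    }
  }
  dist <- if (length(rows)) do.call(rbind, rows) else
    empty_distance_restraints()
  class(dist) <- c("distance_restraints", "data.frame")

  at <- truth$atoms
  prot <- at[at$chain != ligand_chain, ]
  hb <- list()
  for (ch in unique(prot$chain)) {
    res <- sort(unique(prot$resno[prot$chain == ch]))
    for (r in res) {
      don <- r + 4L
      if (!don %in% res) next
      if (!any(prot$chain == ch & prot$resno == don & prot$atname == "H"))
        next
      hb[[length(hb) + 1L]] <- data.frame(chain_d = ch, resno_d = don,
                                          chain_a = ch, resno_a = r,
                                          stringsAsFactors = FALSE)
    }
  }
  if (length(hb)) {
    dist <- rbind(dist, make_hbond_restraints(do.call(rbind, hb)))
    class(dist) <- c("distance_restraints", "data.frame")
  }

  dih <- list()
  for (ch in unique(prot$chain)) {
    res <- sort(unique(prot$resno[prot$chain == ch]))
    for (r in res) {
      if ((r - 1L) %in% res) {
        idx <- c(which(at$chain == ch & at$resno == r - 1L & at$atname == "C"),
                 which(at$chain == ch & at$resno == r & at$atname == "N"),
                 which(at$chain == ch & at$resno == r & at$atname == "CA"),
                 which(at$chain == ch & at$resno == r & at$atname == "C"))
        dih[[length(dih) + 1L]] <- dihedral_restraint(
          ch, c(r - 1L, r, r, r), c("C", "N", "CA", "C"),
          target = torsion_angles(xyz, matrix(idx, 1L)), half_width = 20,
          angle_name = "phi")
      }
      if ((r + 1L) %in% res) {
        idx <- c(which(at$chain == ch & at$resno == r & at$atname == "N"),
                 which(at$chain == ch & at$resno == r & at$atname == "CA"),
                 which(at$chain == ch & at$resno == r & at$atname == "C"),
                 which(at$chain == ch & at$resno == r + 1L & at$atname == "N"))
        dih[[length(dih) + 1L]] <- dihedral_restraint(
          ch, c(r, r, r, r + 1L), c("N", "CA", "C", "N"),
          target = torsion_angles(xyz, matrix(idx, 1L)), half_width = 20,
          angle_name = "psi")
      }
    }
  }
  dihr <- if (length(dih)) do.call(rbind, dih) else
    empty_dihedral_restraints()
  class(dihr) <- c("dihedral_restraints", "data.frame")
  restraint_set(dist, dihr,
                provenance = sprintf(
                  "derived from truth (cutoff %.2f A, noise %.2f, seed %d)",
                  cutoff, noise, as.integer(seed)))
}

#' Fixture configuration
#'
#' The study conditions emulated by the synthetic complex: a 30-residue
#' amphipathic helical fragment with an ideal alpha-helical backbone, a
#' rigid chiral ligand docked against its methyl face, restraints derived
#' from the true coordinates with the experimental intensity classes, and
#' Gaussian-perturbed starting structures.
#'
#' @param sequence One-letter protein sequence.
#' @param phi,psi Helix backbone torsions (degrees).
#' @param ligand_handedness `"S"` or `"R"`.
#' @param restraint_cutoff Restraint derivation cutoff (A, <= 6).
#' @param noise Bound-widening noise SD (A), see [derive_restraints()].
#' @param perturbation_rms Start-structure perturbation (A RMS per atom).
#' @param n_starts Number of perturbed starting structures stored.
#' @param anchor_resno Residue whose C-beta direction the ligand is docked
#'   along (`NULL`: the methyl residue nearest mid-sequence).
#' @param seed Base seed, recorded in all outputs.
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(sequence = "AEKLLSAMVETIKGAVDALHEMAKTLFEQA",
                           phi = -57, psi = -47,
                           ligand_handedness = c("S", "R"),
                           restraint_cutoff = 5.0, noise = 0,
                           perturbation_rms = 1.0, n_starts = 5L,
                           anchor_resno = NULL, seed = 1L) {
  if (restraint_cutoff > 6.0)
    stop("restraint_cutoff must not exceed 6.0 A")
  structure(list(sequence = sequence, phi = phi, psi = psi,
                 ligand_handedness = match.arg(ligand_handedness),
                 restraint_cutoff = restraint_cutoff, noise = noise,
                 perturbation_rms = perturbation_rms,
                 n_starts = as.integer(n_starts),
                 anchor_resno = anchor_resno, seed = as.integer(seed)),
            class = "fixture_config")
}

rotation_between <- function(u, v) {
  # proper rotation taking unit vector u onto unit vector v (Rodrigues)
  w <- c(u[2L] * v[3L] - u[3L] * v[2L], u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  s <- sqrt(sum(w^2))
  c0 <- sum(u * v)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate half a turn about any perpendicular axis
    p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- unit3(p - sum(p * u) * u)
    return(2 * outer(w, w) - diag(3))
  }
  K <- rbind(c(0, -w[3L], w[2L]), c(w[3L], 0, -w[1L]), c(-w[2L], w[1L], 0))
  diag(3) + K + K %*% K * ((1 - c0) / s^2)
}

dock_ligand <- function(helix, ligand, anchor_resno) {
  at <- helix$atoms
  ca <- coords(helix)[at$resno == anchor_resno & at$atname == "CA", ]
  cb <- coords(helix)[at$resno == anchor_resno & at$atname == "CB", ]
  dir <- unit3(cb - ca)
  # orient the ligand's proton-rich face (methyl + methine protons that
  # carry the intermolecular NOEs) toward the helix
  lx <- coords(ligand)
  ctr <- colMeans(lx)
  lat <- ligand$atoms$atname
  face <- colMeans(lx[lat %in% c("HM1", "HM2", "HM3", "HK1", "HK2", "HK3",
                                 "H31", "H1"), , drop = FALSE])
  R <- rotation_between(unit3(face - ctr), -dir)
  lx <- sweep(sweep(lx, 2L, ctr) %*% t(R), 2L, ctr, "+")
  ligand <- set_coords(ligand, lx)
  lig_heavy <- lx[!is_hydrogen_name(ligand$atoms$atname), , drop = FALSE]
  hel_heavy <- coords(helix)[!is_hydrogen_name(at$atname), , drop = FALSE]
  for (offset in seq(3.0, 8.0, by = 0.25)) {
    target <- cb + offset * dir
    shift <- target - colMeans(lx)
    lh <- sweep(lig_heavy, 2L, shift, "+")
    d2 <- outer(rowSums(hel_heavy^2), rowSums(lh^2), "+") -
      2 * hel_heavy %*% t(lh)
    if (min(d2) >= 3.0^2) {
      return(set_coords(ligand, sweep(lx, 2L, shift, "+")))
    }
  }
  stop("could not place the ligand without steric overlap")
}

#' Generate a synthetic complex fixture
#'
#' Builds the true complex (ideal helix + docked toy ligand), measures the
#' covalent topology from it, derives the restraint set from the true
#' coordinates, and draws perturbed starting structures — a fully
#' deterministic function of its configuration. With zero bound noise the
#' truth satisfies every restraint exactly (zero restraint energy), the
#' ground-truth contract the refinement and validation tests rely on.
#'
#' @param config A [fixture_config()].
#' @return Object of class `nmr_fixture`: `truth`, `restraints`,
#'   `topology`, `starts` (list of perturbed structures), `manifest`
#'   (restraint accounting), `chiral_center`, `config`.
#' @export
make_fixture <- function(config = fixture_config()) {
  helix <- make_ideal_helix(config$sequence, config$phi, config$psi)
  lig <- make_toy_ligand(config$ligand_handedness)
  anchor <- config$anchor_resno
  if (is.null(anchor)) {
    at <- helix$atoms
    methyl <- sort(unique(at$resno[at$resname %in% METHYL_RESIDUES]))
    anchor <- methyl[which.min(abs(methyl - max(at$resno) / 2))]
  }
  lig_placed <- dock_ligand(helix, lig$structure, anchor)
  truth <- nmr_structure(rbind(helix$atoms, lig_placed$atoms))

  prot_topo <- measure_topology(
    truth, protein_bond_table(truth),
    extra_impropers = omega_impropers(truth))
  # measure the ligand topology on the docked copy, with its torsion terms
  lig_topo <- measure_topology(
    truth, bond_table(lig_placed, lig$bonds),
    k_improper = LIGAND_K_IMPROPER,
    extra_impropers = rbind(c("O1", "C1", "C3", "C4"),
                            c("O1", "C1", "C2", "HM1"),
                            c("C1", "C3", "C4", "HK1"),
                            c("C1", "C3", "N1", "C5"),
                            c("C3", "N1", "C5", "O2"),
                            c("C2", "C1", "O1", "HO1")))
  topology <- merge_topology(prot_topo, lig_topo)

  restraints <- derive_restraints(truth, config$restraint_cutoff,
                                  seed = config$seed, noise = config$noise)
  starts <- lapply(seq_len(config$n_starts), function(k)
    perturb_structure(truth, config$perturbation_rms, config$seed + k))
  structure(list(truth = truth, restraints = restraints,
                 topology = topology, starts = starts,
                 manifest = accounting(restraints, ligand_chain = "L"),
                 chiral_center = lig$center, config = config),
            class = "nmr_fixture")
}

#' @export
print.nmr_fixture <- function(x, ...) {
  cat(sprintf(
    "<nmr_fixture: %d residues + %s ligand, %d distance + %d dihedral restraints, %d starts (seed %d)>\n",
    nchar(x$config$sequence), x$config$ligand_handedness,
    nrow(x$restraints$distance), nrow(x$restraints$dihedral),
    length(x$starts), x$config$seed))
  invisible(x)
}

#' Topologies and starting structures for an enantiomer screen
#'
#' From a fixture whose restraints were derived with one ligand hand,
#' builds the paired inputs for [enantiomer_screen()]: the fixture's own
#' topology plus a copy with the sign of the ligand chirality-enforcing
#' improper targets flipped (bond and angle terms are mirror-invariant),
#' and per-hand starting structures in which the ligand fragment carries
#' the respective hand (the opposite hand's ligand is reflected in place
#' through its own centroid).
#'
#' @param fixture An `nmr_fixture`.
#' @param ligand_chain Ligand chain identifier.
#' @return List with named lists `topologies` and `starts` (names `"R"`,
#'   `"S"`).
#' @export
fixture_enantiomer_inputs <- function(fixture, ligand_chain = "L") {
  hand <- fixture$config$ligand_handedness
  other <- setdiff(c("R", "S"), hand)
  topo_other <- fixture$topology
  li <- topo_other$impropers$ligand
  topo_other$impropers$phi0[li] <- wrap_angle(-topo_other$impropers$phi0[li])
  s <- fixture$truth
  at <- s$atoms
  xyz <- coords(s)
  lig <- at$chain == ligand_chain
  zc <- mean(xyz[lig, 3L])
  xyz[lig, 3L] <- 2 * zc - xyz[lig, 3L]
  start_other <- set_coords(s, xyz)
  topologies <- stats::setNames(list(fixture$topology, topo_other),
                                c(hand, other))
  starts <- stats::setNames(list(fixture$truth, start_other), c(hand, other))
  list(topologies = topologies[c("R", "S")], starts = starts[c("R", "S")])
}

#' Mirror a fixture through the z = 0 plane
#'
#' Reflects truth and starts, negates every improper equilibrium and flips
#' the dihedral-restraint targets, mapping an R fixture onto its exact S
#' mirror image (and vice versa) with identical energies.
#'
#' @param fixture An `nmr_fixture`.
#' @return The mirrored fixture.
#' @export
mirror_fixture <- function(fixture) {
  flip <- function(s) {
    xyz <- coords(s)
    xyz[, 3L] <- -xyz[, 3L]
    set_coords(s, xyz)
  }
  fixture$truth <- flip(fixture$truth)
  fixture$starts <- lapply(fixture$starts, flip)
  if (!is.null(fixture$topology$impropers))
    fixture$topology$impropers$phi0 <-
      wrap_angle(-fixture$topology$impropers$phi0)
  fixture$restraints$dihedral$target <-
    wrap_angle(-fixture$restraints$dihedral$target)
  fixture$config$ligand_handedness <-
    if (fixture$config$ligand_handedness == "S") "R" else "S"
  fixture
}
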