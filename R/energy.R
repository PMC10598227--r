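#' Restraint energy model
#'
#' Force constants and shape parameters of the restraint potential. The NOE
#' term is a flat-bottom soft-square: zero inside the bounds, harmonic
#' (`k_noe * v^2`) for violations up to `soft_switch`, then linear with
#' matched value and slope, so energy and first derivative are continuous
#' everywhere. Dihedral restraints are harmonic in the wrapped excess
#' violation (radians). All covalent terms of ligand atoms are multiplied
#' by `ligand_scale`, the calibrated compromise that enforces ligand
#' geometry without overwhelming the annealing.
#'
#' @param k_noe NOE force constant, energy/A^2.
#' @param k_dihedral Dihedral force constant, energy/rad^2.
#' @param soft_switch Violation (A) at which the NOE term switches from
#'   harmonic to linear.
#' @param ligand_scale Multiplier in (0, 1] on ligand covalent terms.
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(k_noe = 50, k_dihedral = 200, soft_switch = 1.0,
                         ligand_scale = 0.2) {
  stopifnot(k_noe > 0, k_dihedral > 0, soft_switch > 0,
            ligand_scale > 0, ligand_scale <= 1)
  structure(list(k_noe = k_noe, k_dihedral = k_dihedral,
                 soft_switch = soft_switch, ligand_scale = ligand_scale),
            class = "energy_model")
}

#' Covalent topology
#'
#' Harmonic bond, angle and improper terms with equilibrium values and
#' force constants; impropers (torsions over arbitrary atom quadruples)
#' encode planarity and chirality. Atoms are identified by
#' (chain, resno, atom name); the logical `ligand` column marks terms whose
#' force constants are scaled by the model's `ligand_scale`.
#'
#' @param bonds data.frame: `chain_1,resno_1,atom_1,chain_2,resno_2,atom_2,
#'   r0` (A, > 0), `k`, `ligand`.
#' @param angles data.frame: three atom triples, `theta0` (degrees), `k`,
#'   `ligand`.
#' @param impropers data.frame: four atom quadruples, `phi0` (degrees),
#'   `k`, `ligand`.
#' @return Object of class `covalent_topology`.
#' @export
covalent_topology <- function(bonds = NULL, angles = NULL, impropers = NULL) {
  if (!is.null(bonds) && nrow(bonds) > 0L && any(bonds$r0 <= 0))
    stop("equilibrium bond lengths must be positive")
  structure(list(bonds = bonds, angles = angles, impropers = impropers),
            class = "covalent_topology")
}

#' @export
print.covalent_topology <- function(x, ...) {
  nr <- function(d) if (is.null(d)) 0L else nrow(d)
  cat(sprintf("<covalent_topology: %d bonds, %d angles, %d impropers>\n",
              nr(x$bonds), nr(x$angles), nr(x$impropers)))
  invisible(x)
}

#' Combine two topologies
#' @param a,b [covalent_topology()] objects.
#' @return Their union.
#' @export
merge_topology <- function(a, b) {
  cat2 <- function(x, y) if (is.null(x)) y else if (is.null(y)) x else
    rbind(x, y)
  covalent_topology(cat2(a$bonds, b$bonds), cat2(a$angles, b$angles),
                    cat2(a$impropers, b$impropers))
}

atom_index_lookup <- function(structure) {
  at <- structure$atoms
  stats::setNames(seq_len(nrow(at)), paste(at$chain, at$resno, at$atname))
}

topo_indices <- function(d, n_atoms_cols, lookup, what) {
  idx <- matrix(0L, nrow(d), n_atoms_cols)
  for (k in seq_len(n_atoms_cols)) {
    key <- paste(d[[paste0("chain_", k)]], d[[paste0("resno_", k)]],
                 d[[paste0("atom_", k)]])
    idx[, k] <- lookup[key]
    if (anyNA(idx[, k]))
      stop("missing atom in ", what, " term: ", key[is.na(idx[, k])][1L])
  }
  idx
}

# Resolve restraints + topology against a structure's atom table once;
# the compiled system is reused for every energy/gradient evaluation and is
# valid for any structure sharing that atom table.
compile_system <- function(structure, restraints = NULL, topology = NULL,
                           model = energy_model(),
                           method = c("r6_average", "r6_sum")) {
  method <- match.arg(method)
  lookup <- atom_index_lookup(structure)
  sys <- list(n = nrow(structure$atoms), model = model, method = method)

  dist <- if (!is.null(restraints)) restraints$distance else NULL
  if (!is.null(dist) && nrow(dist) > 0L) {
    pl <- vector("list", nrow(dist))
    for (r in seq_len(nrow(dist))) {
      sel <- distance_restraint_selectors(dist[r, ])
      pl[[r]] <- expand_pair(sel[[1L]], sel[[2L]], structure)
    }
    npairs <- vapply(pl, nrow, integer(1L))
    pairs <- do.call(rbind, pl)
    sys$dist <- list(pi = pairs[, 1L], pj = pairs[, 2L],
                     rid = rep.int(seq_along(npairs), npairs),
                     npairs = npairs, lower = dist$lower, upper = dist$upper,
                     origin = dist$origin)
  }

  dihr <- if (!is.null(restraints)) restraints$dihedral else NULL
  if (!is.null(dihr) && nrow(dihr) > 0L) {
    quads <- matrix(0L, nrow(dihr), 4L)
    for (r in seq_len(nrow(dihr)))
      quads[r, ] <- dihedral_restraint_atoms(dihr[r, ], structure)
    sys$dihr <- list(quads = quads, target = dihr$target,
                     hw = dihr$half_width)
  }

  if (!is.null(topology)) {
    scale_k <- function(d) d$k * ifelse(d$ligand, model$ligand_scale, 1)
    if (!is.null(topology$bonds) && nrow(topology$bonds) > 0L) {
      b <- topology$bonds
      sys$bonds <- list(idx = topo_indices(b, 2L, lookup, "bond"),
                        r0 = b$r0, k = scale_k(b))
    }
    if (!is.null(topology$angles) && nrow(topology$angles) > 0L) {
      a <- topology$angles
      sys$angles <- list(idx = topo_indices(a, 3L, lookup, "angle"),
                         th0 = a$theta0 * pi / 180, k = scale_k(a))
    }
    if (!is.null(topology$impropers) && nrow(topology$impropers) > 0L) {
      im <- topology$impropers
      sys$imps <- list(idx = topo_indices(im, 4L, lookup, "improper"),
                       phi0 = im$phi0, k = scale_k(im))
    }
  }
  sys$scatter <- compile_scatter(sys)
  sys
}

# The gradient is assembled by scatter-adding per-term contributions onto
# atoms. The atom-index concatenation is fixed at compile time (it must
# mirror the acc_add order in energy_gradient), so the sort order and group
# boundaries of the reduction can be precomputed once.
scatter_atom_order <- function(sys) {
  idx <- list()
  if (!is.null(sys$dist)) idx <- c(idx, list(sys$dist$pi, sys$dist$pj))
  if (!is.null(sys$dihr))
    idx <- c(idx, lapply(1:4, function(k) sys$dihr$quads[, k]))
  if (!is.null(sys$bonds))
    idx <- c(idx, list(sys$bonds$idx[, 1L], sys$bonds$idx[, 2L]))
  if (!is.null(sys$angles))
    idx <- c(idx, lapply(c(1L, 3L, 2L), function(k) sys$angles$idx[, k]))
  if (!is.null(sys$imps))
    idx <- c(idx, lapply(1:4, function(k) sys$imps$idx[, k]))
  unlist(idx)
}

compile_scatter <- function(sys) {
  all_idx <- scatter_atom_order(sys)
  if (length(all_idx) == 0L) return(NULL)
  ord <- order(all_idx)
  sorted <- all_idx[ord]
  new_grp <- which(c(TRUE, sorted[-1L] != sorted[-length(sorted)]))
  list(ord = ord, starts = new_grp,
       ends = c(new_grp[-1L] - 1L, length(sorted)),
       uids = sorted[new_grp])
}

new_accumulator <- function() {
  env <- new.env(parent = emptyenv())
  env$val <- list()
  env
}

acc_add <- function(acc, V) {
  acc$val[[length(acc$val) + 1L]] <- V
  invisible(acc)
}

acc_reduce <- function(acc, sys) {
  G <- matrix(0, sys$n, 3L)
  sc <- sys$scatter
  if (is.null(sc)) return(G)
  V <- do.call(rbind, acc$val)[sc$ord, , drop = FALSE]
  for (c in 1:3) {
    cs <- cumsum(V[, c])
    G[sc$uids, c] <- cs[sc$ends] - cs[sc$starts] + V[sc$starts, c]
  }
  G
}

# flat-bottom soft-square energy and dE/dv for non-negative violation v
soft_square <- function(v, k, s) {
  harm <- v <= s
  e <- ifelse(harm, k * v^2, k * s^2 + 2 * k * s * (v - s))
  de <- ifelse(harm, 2 * k * v, 2 * k * s)
  list(e = e, de = de)
}

# torsion angles (radians) and, optionally, their Cartesian gradients
torsion_rad_grad <- function(xyz, quads, grad = TRUE) {
  b1 <- xyz[quads[, 2L], , drop = FALSE] - xyz[quads[, 1L], , drop = FALSE]
  b2 <- xyz[quads[, 3L], , drop = FALSE] - xyz[quads[, 2L], , drop = FALSE]
  b3 <- xyz[quads[, 4L], , drop = FALSE] - xyz[quads[, 3L], , drop = FALSE]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  phi <- atan2(rowSums(cross3(n1, n2) * b2) / nb2, rowSums(n1 * n2))
  out <- list(phi = phi)
  if (grad) {
    n1sq <- rowSums(n1^2)
    n2sq <- rowSums(n2^2)
    dA <- -n1 * (nb2 / n1sq)      # dphi/dr1
    dD <- n2 * (nb2 / n2sq)       # dphi/dr4
    s1 <- rowSums(b1 * b2) / nb2^2
    s2 <- rowSums(b3 * b2) / nb2^2
    dB <- -(1 + s1) * dA + s2 * dD # dphi/dr2
    dC <- s1 * dA - (1 + s2) * dD  # dphi/dr3
    out$d <- list(dA, dB, dC, dD)
  }
  out
}

# total energy breakdown and analytic gradient for a compiled system
energy_gradient <- function(xyz, sys, grad = TRUE) {
  acc <- if (grad) new_accumulator() else NULL
  e_noe <- 0
  e_dih <- 0
  e_cov <- 0
  model <- sys$model

  if (!is.null(sys$dist)) {
    ds <- sys$dist
    dv <- xyz[ds$pi, , drop = FALSE] - xyz[ds$pj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    if (any(d == 0)) stop("coincident atoms in distance restraint")
    s6 <- d^(-6)
    S <- as.numeric(rowsum(s6, ds$rid))  # rid is 1..R, already sorted
    if (sys$method == "r6_average") S <- S / ds$npairs
    deff <- S^(-1 / 6)
    signed <- ifelse(deff > ds$upper, deff - ds$upper,
              ifelse(deff < ds$lower, deff - ds$lower, 0))
    ss <- soft_square(abs(signed), model$k_noe, model$soft_switch)
    e_noe <- sum(ss$e)
    if (grad) {
      dE_ddeff <- ss$de * sign(signed)
      # d(deff)/d(d_p) = deff^7 * d_p^-7  (over n for the averaged form)
      coef <- dE_ddeff * deff^7
      if (sys$method == "r6_average") coef <- coef / ds$npairs
      cp <- coef[ds$rid] * d^(-7)
      Fp <- dv * (cp / d)
      acc_add(acc, Fp)
      acc_add(acc, -Fp)
    }
  }

  if (!is.null(sys$dihr)) {
    dr <- sys$dihr
    tg <- torsion_rad_grad(xyz, dr$quads, grad)
    delta <- wrap_angle(tg$phi * 180 / pi - dr$target)     # degrees
    v <- pmax(0, abs(delta) - dr$hw) * pi / 180            # radians
    e_dih <- sum(model$k_dihedral * v^2)
    if (grad) {
      dE_dphi <- 2 * model$k_dihedral * v * sign(delta)    # per radian
      for (k in 1:4)
        acc_add(acc, tg$d[[k]] * dE_dphi)
    }
  }

  if (!is.null(sys$bonds)) {
    bd <- sys$bonds
    dv <- xyz[bd$idx[, 1L], , drop = FALSE] - xyz[bd$idx[, 2L], , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    e_cov <- e_cov + sum(bd$k * (d - bd$r0)^2)
    if (grad) {
      Fp <- dv * (2 * bd$k * (d - bd$r0) / d)
      acc_add(acc, Fp)
      acc_add(acc, -Fp)
    }
  }

  if (!is.null(sys$angles)) {
    an <- sys$angles
    u <- xyz[an$idx[, 1L], , drop = FALSE] - xyz[an$idx[, 2L], , drop = FALSE]
    v <- xyz[an$idx[, 3L], , drop = FALSE] - xyz[an$idx[, 2L], , drop = FALSE]
    nu <- sqrt(rowSums(u^2))
    nv <- sqrt(rowSums(v^2))
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    e_cov <- e_cov + sum(an$k * (th - an$th0)^2)
    if (grad) {
      sth <- pmax(sqrt(1 - cth^2), 1e-8)
      uh <- u / nu
      vh <- v / nv
      dE_dth <- 2 * an$k * (th - an$th0)
      g1 <- (uh * cth - vh) / (nu * sth) * dE_dth
      g3 <- (vh * cth - uh) / (nv * sth) * dE_dth
      acc_add(acc, g1)
      acc_add(acc, g3)
      acc_add(acc, -(g1 + g3))
    }
  }

  if (!is.null(sys$imps)) {
    im <- sys$imps
    tg <- torsion_rad_grad(xyz, im$idx, grad)
    delta <- wrap_angle(tg$phi * 180 / pi - im$phi0) * pi / 180  # radians
    e_cov <- e_cov + sum(im$k * delta^2)
    if (grad) {
      dE_dphi <- 2 * im$k * delta
      for (k in 1:4)
        acc_add(acc, tg$d[[k]] * dE_dphi)
    }
  }

  out <- list(noe = e_noe, dihedral = e_dih, covalent = e_cov,
              total = e_noe + e_dih + e_cov)
  if (grad) out$grad <- acc_reduce(acc, sys)
  out
}

breakdown_of <- function(ev) {
  structure(list(noe = ev$noe, dihedral = ev$dihedral,
                 covalent = ev$covalent, total = ev$total),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: total %.4g (noe %.4g, dihedral %.4g, covalent %.4g)\n",
              x$total, x$noe, x$dihedral, x$covalent))
  invisible(x)
}

#' NOE restraint energy
#'
#' Flat-bottom soft-square energy of a single distance restraint: zero
#' inside the bounds, `k_noe * v^2` for violations `v` up to the switch,
#' then linear continuation with matched value and slope (`2 k s`).
#'
#' @param restraint One-row distance restraint.
#' @param structure An [nmr_structure()].
#' @param model An [energy_model()].
#' @param method Effective-distance convention.
#' @return Energy (same units as `k_noe * A^2`).
#' @export
noe_energy <- function(restraint, structure, model = energy_model(),
                       method = c("r6_average", "r6_sum")) {
  v <- distance_violation(restraint, structure, match.arg(method))
  soft_square(v, model$k_noe, model$soft_switch)$e
}

#' Dihedral restraint energy
#'
#' Harmonic in the wrapped excess violation (in radians): zero inside the
#' band, `k_dihedral * v^2` beyond.
#'
#' @inheritParams noe_energy
#' @param restraint One-row dihedral restraint.
#' @return Energy.
#' @export
dihedral_energy <- function(restraint, structure, model = energy_model()) {
  v <- dihedral_violation(restraint, structure) * pi / 180
  model$k_dihedral * v^2
}

#' Covalent (bond + angle + improper) energy
#'
#' Harmonic terms over the topology; ligand-flagged terms are scaled by
#' `ligand_scale`.
#'
#' @param structure An [nmr_structure()].
#' @param topology A [covalent_topology()].
#' @param model An [energy_model()].
#' @return Energy.
#' @export
covalent_energy <- function(structure, topology, model = energy_model()) {
  sys <- compile_system(structure, NULL, topology, model)
  energy_gradient(coords(structure), sys, grad = FALSE)$covalent
}

#' Total restrained energy with breakdown
#'
#' @param structure An [nmr_structure()].
#' @param restraints A [restraint_set()] (or `NULL`).
#' @param topology A [covalent_topology()] (or `NULL`).
#' @param model An [energy_model()].
#' @param method Effective-distance convention.
#' @return `energy_breakdown` with components `noe`, `dihedral`,
#'   `covalent`, `total` (their exact sum).
#' @export
total_energy <- function(structure, restraints = NULL, topology = NULL,
                         model = energy_model(),
                         method = c("r6_average", "r6_sum")) {
  sys <- compile_system(structure, restraints, topology, model,
                        match.arg(method))
  breakdown_of(energy_gradient(coords(structure), sys, grad = FALSE))
}
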