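#' Refinement configuration
#'
#' Controls the perturb-and-minimize protocol: a pool of independent runs,
#' each starting from the input structure perturbed by isotropic Gaussian
#' coordinate noise, minimized by gradient descent, with the lowest-energy
#' structures kept. Run `r` reseeds the generator at `seed + r`, so pools
#' are exactly reproducible given the config.
#'
#' @param max_iterations Iteration cap for the minimizer.
#' @param gradient_tolerance Terminate when the gradient max-norm falls
#'   below this (energy units per Angstrom).
#' @param perturbation_rms Per-atom RMS displacement (A) of the Gaussian
#'   start perturbation.
#' @param seed Base RNG seed.
#' @param pool_size Number of independent runs.
#' @param keep_n Number of lowest-energy structures selected
#'   (`keep_n <= pool_size`).
#' @param restarts Maximum number of noise-injection restarts per
#'   minimization: when the descent stalls above `restart_threshold`, the
#'   current structure is re-perturbed by `restart_noise` (A RMS) and
#'   re-minimized, keeping the lower-energy outcome — the Cartesian
#'   stand-in for the basin hopping that annealing provides.
#' @param restart_noise RMS amplitude (A) of the restart perturbation.
#' @param restart_threshold Total energy below which a result is accepted
#'   without further restarts.
#' @return Object of class `refine_config`.
#' @export
refine_config <- function(max_iterations = 2000L, gradient_tolerance = 0.02,
                          perturbation_rms = 1.0, seed = 1L,
                          pool_size = 20L, keep_n = 10L,
                          restarts = 4L, restart_noise = 0.5,
                          restart_threshold = 1.0) {
  stopifnot(gradient_tolerance > 0, keep_n <= pool_size, pool_size >= 1L,
            perturbation_rms >= 0, restarts >= 0L, restart_noise >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 perturbation_rms = perturbation_rms,
                 seed = as.integer(seed),
                 pool_size = as.integer(pool_size),
                 keep_n = as.integer(keep_n),
                 restarts = as.integer(restarts),
                 restart_noise = restart_noise,
                 restart_threshold = restart_threshold),
            class = "refine_config")
}

#' Perturb a structure with isotropic Gaussian coordinate noise
#'
#' Per-coordinate noise with standard deviation `rms / sqrt(3)`, so the
#' expected per-atom displacement RMS equals `rms`.
#'
#' @param structure An [nmr_structure()].
#' @param rms Target per-atom RMS displacement in Angstrom.
#' @param seed RNG seed (Mersenne-Twister).
#' @return Perturbed structure.
#' @export
perturb_structure <- function(structure, rms, seed) {
  xyz <- coords(structure)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  noise <- matrix(stats::rnorm(length(xyz), sd = rms / sqrt(3)),
                  ncol = 3L)
  set_coords(structure, xyz + noise)
}

#' Gradient-descent minimization of the restrained energy
#'
#' Steepest descent with a backtracking line search (Armijo condition) and
#' a Barzilai-Borwein initial step length. The energy over accepted steps
#' is monotone non-increasing; iteration stops when the gradient max-norm
#' drops below the tolerance or the iteration cap is reached.
#'
#' @param start An [nmr_structure()].
#' @param restraints A [restraint_set()] (or `NULL`).
#' @param topology A [covalent_topology()] (or `NULL`).
#' @param model An [energy_model()].
#' @param config A [refine_config()].
#' @param method Effective-distance convention for NOE terms.
#' @return List: `structure` (minimized), `breakdown`
#'   (`energy_breakdown`), `trace` (energy per accepted step),
#'   `iterations`, `converged`, `grad_norm`.
#' @export
minimize_structure <- function(start, restraints = NULL, topology = NULL,
                               model = energy_model(),
                               config = refine_config(),
                               method = c("r6_average", "r6_sum")) {
  method <- match.arg(method)
  sys <- compile_system(start, restraints, topology, model, method)
  minimize_compiled(start, sys, config)
}

minimize_compiled <- function(start, sys, config) {
  best <- descend_compiled(start, sys, config)
  n_restarts <- 0L
  while (n_restarts < config$restarts &&
         best$breakdown$total > config$restart_threshold) {
    n_restarts <- n_restarts + 1L
    s2 <- perturb_structure(best$structure, config$restart_noise,
                            config$seed + 900000L + n_restarts)
    cand <- descend_compiled(s2, sys, config)
    if (cand$breakdown$total < best$breakdown$total) best <- cand
  }
  best$restarts_used <- n_restarts
  best
}

descend_compiled <- function(start, sys, config) {
  xyz <- coords(start)
  ev <- energy_gradient(xyz, sys)
  if (!is.finite(ev$total) || !all(is.finite(ev$grad)))
    stop("non-finite energy or gradient at iteration 0")
  trace <- ev$total
  step <- 1e-4
  g_prev <- NULL
  x_prev <- NULL
  it <- 0L
  gnorm <- max(abs(ev$grad))
  while (it < config$max_iterations && gnorm > config$gradient_tolerance) {
    it <- it + 1L
    # Barzilai-Borwein step from the previous accepted move
    if (!is.null(g_prev)) {
      sx <- xyz - x_prev
      sg <- ev$grad - g_prev
      denom <- sum(sx * sg)
      if (is.finite(denom) && denom > 0) {
        step <- sum(sx * sx) / denom
        step <- min(max(step, 1e-7), 1.0)
      }
    }
    gsq <- sum(ev$grad^2)
    accepted <- FALSE
    for (bt in 1:30) {
      xn <- xyz - step * ev$grad
      en <- energy_gradient(xn, sys, grad = FALSE)
      if (is.finite(en$total) && en$total <= ev$total - 1e-4 * step * gsq) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    x_prev <- xyz
    g_prev <- ev$grad
    xyz <- xn
    ev <- energy_gradient(xyz, sys)
    if (!is.finite(ev$total) || !all(is.finite(ev$grad)))
      stop("non-finite energy or gradient at iteration ", it)
    trace <- c(trace, ev$total)
    gnorm <- max(abs(ev$grad))
  }
  list(structure = set_coords(start, xyz), breakdown = breakdown_of(ev),
       trace = trace, iterations = it,
       converged = gnorm <= config$gradient_tolerance, grad_norm = gnorm)
}

#' Generate a pool of independently refined structures
#'
#' Runs `pool_size` independent perturb-and-minimize calculations from
#' `start`, run `r` using seed `seed + r`; results are fully reproducible
#' given the config.
#'
#' @inheritParams minimize_structure
#' @return List of class `refine_pool`; each element has `structure`,
#'   `breakdown`, `run_index`, `seed`, `converged`, `iterations`.
#' @export
generate_pool <- function(start, restraints = NULL, topology = NULL,
                          model = energy_model(), config = refine_config(),
                          method = c("r6_average", "r6_sum")) {
  method <- match.arg(method)
  sys <- compile_system(start, restraints, topology, model, method)
  pool <- vector("list", config$pool_size)
  for (r in seq_len(config$pool_size)) {
    run_seed <- config$seed + r
    s0 <- if (config$perturbation_rms > 0) {
      perturb_structure(start, config$perturbation_rms, run_seed)
    } else {
      start
    }
    fit <- minimize_compiled(s0, sys, config)
    pool[[r]] <- list(structure = fit$structure, breakdown = fit$breakdown,
                      run_index = r, seed = run_seed,
                      converged = fit$converged, iterations = fit$iterations)
  }
  class(pool) <- "refine_pool"
  pool
}

#' Pool energies as a data.frame
#' @param pool A `refine_pool`.
#' @return data.frame with run index, seed and energy components.
#' @export
pool_energies <- function(pool) {
  data.frame(run_index = vapply(pool, `[[`, integer(1L), "run_index"),
             seed = vapply(pool, function(p) as.integer(p$seed), integer(1L)),
             noe = vapply(pool, function(p) p$breakdown$noe, numeric(1L)),
             dihedral = vapply(pool, function(p) p$breakdown$dihedral,
                               numeric(1L)),
             covalent = vapply(pool, function(p) p$breakdown$covalent,
                               numeric(1L)),
             total = vapply(pool, function(p) p$breakdown$total, numeric(1L)))
}

#' Select the lowest-energy members of a pool
#'
#' Stable sort on the energy key with run-index tie-breaking, keeping the
#' first `keep_n` — the "N structures with the lowest NOE energies"
#' selection rule.
#'
#' @param pool A `refine_pool` from [generate_pool()].
#' @param keep_n Number of structures to keep (`<=` pool size).
#' @param key `"noe"` or `"total"`.
#' @return An [nmr_ensemble()]; attribute `"selection"` holds the selected
#'   run indices and energies.
#' @export
select_lowest <- function(pool, keep_n, key = c("noe", "total")) {
  key <- match.arg(key)
  if (keep_n > length(pool))
    stop("keep_n (", keep_n, ") exceeds pool size (", length(pool), ")")
  en <- pool_energies(pool)
  ord <- order(en[[key]], en$run_index)
  sel <- ord[seq_len(keep_n)]
  ens <- nmr_ensemble(lapply(pool[sel], `[[`, "structure"))
  attr(ens, "selection") <- en[sel, ]
  ens
}

#' Restrained ensemble refinement
#'
#' The package's model-fitting entry point: generates a pool of
#' perturb-and-minimize runs against the restraints and covalent topology,
#' selects the `keep_n` lowest-energy structures, and returns a fitted
#' object with the ensemble, the pool energy table and the configuration.
#'
#' @inheritParams minimize_structure
#' @param select_key Energy key used for selection (`"noe"` or
#'   `"total"`).
#' @return Object of class `noe_refit` with elements `ensemble`
#'   ([nmr_ensemble()]), `pool` (energy data.frame), `selection`,
#'   `restraints`, `model`, `config`, `method`.
#' @examples
#' \donttest{
#' fx <- make_fixture(fixture_config(sequence = "AKLALEAMVKQ", seed = 7))
#' fit <- refine_ensemble(fx$truth, fx$restraints, fx$topology,
#'                        config = refine_config(pool_size = 4, keep_n = 2,
#'                                               seed = 7))
#' print(fit)
#' }
#' @export
refine_ensemble <- function(start, restraints, topology = NULL,
                            model = energy_model(),
                            config = refine_config(),
                            method = c("r6_average", "r6_sum"),
                            select_key = c("noe", "total")) {
  method <- match.arg(method)
  select_key <- match.arg(select_key)
  pool <- generate_pool(start, restraints, topology, model, config, method)
  ens <- select_lowest(pool, config$keep_n, select_key)
  structure(list(ensemble = ens, pool = pool_energies(pool),
                 selection = attr(ens, "selection"),
                 restraints = restraints, topology = topology,
                 model = model, config = config, method = method,
                 select_key = select_key),
            class = "noe_refit")
}

#' @export
print.noe_refit <- function(x, ...) {
  cat(sprintf("Restrained refinement: %d structures calculated, %d with the lowest %s energies selected\n",
              nrow(x$pool), length(x$ensemble$models), x$select_key))
  cat(sprintf("  selected %s energy range: %.3g - %.3g\n", x$select_key,
              min(x$selection[[x$select_key]]),
              max(x$selection[[x$select_key]])))
  invisible(x)
}

#' @export
summary.noe_refit <- function(object, thresholds = c(distance = 0.2,
                                                     dihedral = 2), ...) {
  rep <- violation_report(object$ensemble, object$restraints,
                          thresholds = thresholds)
  out <- list(fit = object, violations = rep,
              pool_summary = summary(object$pool[, c("noe", "total")]))
  class(out) <- "summary.noe_refit"
  out
}

#' @export
print.summary.noe_refit <- function(x, ...) {
  print(x$fit)
  cat("\nPool energies:\n")
  print(x$pool_summary)
  cat("\n")
  print(x$violations)
  invisible(x)
}

#' @export
plot.noe_refit <- function(x, ...) {
  en <- x$pool[[x$select_key]]
  sel <- x$selection$run_index
  graphics::plot(x$pool$run_index, en, xlab = "run index",
                 ylab = paste(x$select_key, "energy"),
                 main = "Refinement pool", pch = 19,
                 col = ifelse(x$pool$run_index %in% sel, "firebrick",
                              "grey50"), ...)
  graphics::legend("topright", pch = 19, col = c("firebrick", "grey50"),
                   legend = c("selected", "rejected"), bty = "n")
  invisible(x)
}

#' R/S enantiomer screen
#'
#' Runs the perturb-and-minimize protocol separately with the R- and
#' S-ligand topologies against the same (enantiomer-derived) restraint
#' set, compares the `n_lowest` NOE energies per hand, and checks the
#' refined chirality of every final structure against its topology's hand,
#' flagging inversions (runs whose ligand flipped hand during refinement).
#' The winning hand is the one with the lower mean of its `n_lowest` NOE
#' energies.
#'
#' @param restraints A [restraint_set()] derived from one enantiomer.
#' @param topologies Named list `list(R = , S = )` of
#'   [covalent_topology()]s differing in the sign of the
#'   chirality-enforcing improper targets.
#' @param starts Named list `list(R = , S = )` of starting
#'   [nmr_structure()]s carrying the respective ligand hand.
#' @param center A [chiral_center()] for the ligand's stereocenter.
#' @param model An [energy_model()].
#' @param config A [refine_config()].
#' @param n_lowest Number of lowest-NOE-energy runs compared per hand.
#' @param method Effective-distance convention.
#' @return Object of class `enantiomer_screen`: `winner`, per-hand energy
#'   tables, `lowest` (the compared energies), and `inversions`.
#' @export
enantiomer_screen <- function(restraints, topologies, starts, center,
                              model = energy_model(),
                              config = refine_config(),
                              n_lowest = min(10L, config$pool_size),
                              method = c("r6_average", "r6_sum")) {
  method <- match.arg(method)
  stopifnot(all(c("R", "S") %in% names(topologies)),
            all(c("R", "S") %in% names(starts)))
  hands <- c("R", "S")
  pools <- list()
  lowest <- list()
  inversions <- data.frame(hand = character(0L), run_index = integer(0L),
                           refined_sign = character(0L))
  for (h in hands) {
    pool <- generate_pool(starts[[h]], restraints, topologies[[h]], model,
                          config, method)
    en <- pool_energies(pool)
    en$hand <- h
    en$refined_sign <- vapply(pool, function(p) {
      chirality_sign(center, p$structure)
    }, character(1L))
    flipped <- en$refined_sign != paste0(h, "_like")
    if (any(flipped))
      inversions <- rbind(inversions,
                          data.frame(hand = h,
                                     run_index = en$run_index[flipped],
                                     refined_sign = en$refined_sign[flipped]))
    pools[[h]] <- en
    lowest[[h]] <- sort(en$noe)[seq_len(n_lowest)]
  }
  means <- vapply(lowest, mean, numeric(1L))
  structure(list(winner = hands[which.min(means)],
                 mean_lowest_noe = means, lowest = lowest,
                 energies = do.call(rbind, pools),
                 inversions = inversions, n_lowest = n_lowest,
                 config = config),
            class = "enantiomer_screen")
}

#' @export
print.enantiomer_screen <- function(x, ...) {
  cat("Enantiomer screen (", x$n_lowest, "lowest NOE energies per hand )\n")
  for (h in names(x$lowest))
    cat(sprintf("  %s: mean %.4g  (range %.4g - %.4g)\n", h,
                x$mean_lowest_noe[[h]], min(x$lowest[[h]]),
                max(x$lowest[[h]])))
  cat("  winner:", x$winner, "\n")
  if (nrow(x$inversions) > 0L) {
    cat("  inversions (refined hand differs from topology):\n")
    print(x$inversions, row.names = FALSE)
  } else {
    cat("  no inversions observed\n")
  }
  invisible(x)
}
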