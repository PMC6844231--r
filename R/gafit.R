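# Genetic-algorithm optimization of per-conformer energy modulations.
#
# The genome is the vector of energy modulations (delta_1 ... delta_N), one
# per conformer, bounded by |delta_i| <= demax.  Fitness is the VCD overlap
# of the composite spectrum built from Boltzmann weights of the modulated
# energies (optionally mixed with the VA overlap).  The all-zero genome --
# i.e. the plain Boltzmann-weight solution -- is always seeded into the
# initial population, so with elitism the fitted overlap can never fall
# below the unfitted one.

#' Genetic-algorithm configuration
#'
#' @param population_size number of genomes per generation (>= 4).
#' @param generations maximum number of generations.
#' @param tournament_size selection tournament size.
#' @param crossover_rate probability of uniform crossover per offspring pair.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sigma per-gene Gaussian mutation width (kcal/mol); the
#'   default `NULL` resolves to `demax/10` at fit time.
#' @param elitism number of best genomes copied unchanged each generation.
#' @param convergence_tol,convergence_window stop early when the best fitness
#'   improves by less than `convergence_tol` over `convergence_window`
#'   generations.
#' @param seed RNG seed; the same seed and inputs give a bit-identical fit.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 128, generations = 300,
                      tournament_size = 3, crossover_rate = 0.7,
                      mutation_rate = 0.2, mutation_sigma = NULL,
                      elitism = 2, convergence_tol = 1e-6,
                      convergence_window = 50, seed = 1) {
  if (population_size < 4) stopf("population_size must be >= 4")
  for (r in c(crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  }
  if (generations < 1) stopf("generations must be >= 1")
  if (elitism < 1 || elitism >= population_size) {
    stopf("elitism must be in [1, population_size)")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 elitism = as.integer(elitism),
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 seed = seed),
            class = "ga_config")
}

# Generic box-constrained GA maximizer.  fitness_fn takes an n_genes x pop
# matrix of genomes and returns one fitness per column.  Equal-fitness ties
# are broken toward the genome of smallest Euclidean norm (the most
# parsimonious deviation from the computed energies).
ga_optimize <- function(n_genes, lower, upper, fitness_fn, ga, init = NULL) {
  P <- ga$population_size
  sigma <- if (is.null(ga$mutation_sigma)) (upper - lower) / 20 else ga$mutation_sigma
  with_seed(ga$seed, {
    pop <- matrix(stats::runif(n_genes * P, lower, upper), nrow = n_genes)
    if (!is.null(init)) {
      init <- matrix(pmin(upper, pmax(lower, init)), nrow = n_genes)
      k <- min(ncol(init), P)
      pop[, seq_len(k)] <- init[, seq_len(k)]
    }
    best_g <- NULL; best_f <- -Inf; best_norm <- Inf
    history <- numeric(0)
    for (gen in seq_len(ga$generations)) {
      fit <- fitness_fn(pop)
      o <- order(fit, decreasing = TRUE)
      # challenge the incumbent: higher fitness wins; equal fitness goes to
      # the smaller-norm genome
      for (j in o[seq_len(min(8L, P))]) {
        fj <- fit[j]
        if (fj > best_f + 1e-12) {
          best_f <- fj; best_g <- pop[, j]; best_norm <- sqrt(sum(pop[, j]^2))
        } else if (fj >= best_f - 1e-12) {
          nj <- sqrt(sum(pop[, j]^2))
          if (nj < best_norm - 1e-12) { best_g <- pop[, j]; best_norm <- nj }
        }
      }
      history[gen] <- best_f
      if (gen >= ga$convergence_window + 1L &&
          history[gen] - history[gen - ga$convergence_window] < ga$convergence_tol) {
        break
      }
      if (gen == ga$generations) break
      elite <- pop[, o[seq_len(ga$elitism)], drop = FALSE]
      n_off <- P - ga$elitism
      # tournament selection, vectorized: for each offspring slot pick two
      # parents as winners of independent tournaments
      pick <- function(n) {
        idx <- matrix(sample.int(P, n * ga$tournament_size, replace = TRUE),
                      nrow = ga$tournament_size)
        fm <- matrix(fit[idx], nrow = ga$tournament_size)
        win <- apply(fm, 2, which.max)
        idx[cbind(win, seq_len(n))]
      }
      p1 <- pick(n_off); p2 <- pick(n_off)
      a <- pop[, p1, drop = FALSE]; b <- pop[, p2, drop = FALSE]
      do_cx <- stats::runif(n_off) < ga$crossover_rate
      if (any(do_cx)) {
        mask <- matrix(stats::runif(n_genes * sum(do_cx)) < 0.5,
                       nrow = n_genes)
        ac <- a[, do_cx, drop = FALSE]; bc <- b[, do_cx, drop = FALSE]
        ac[mask] <- bc[mask]
        a[, do_cx] <- ac
      }
      mut <- matrix(stats::runif(n_genes * n_off) < ga$mutation_rate,
                    nrow = n_genes)
      if (any(mut)) {
        a[mut] <- a[mut] + stats::rnorm(sum(mut), 0, sigma)
        a[] <- pmin(upper, pmax(lower, a))
      }
      pop <- cbind(elite, a)
    }
    list(genome = best_g, fitness = best_f, history = history,
         generations_run = length(history))
  })
}

# Shared fitness machinery: precompute masked experimental vectors and the
# broadened conformer matrices once, then score whole populations with one
# matrix product per generation.
make_fitness <- function(ensemble, exp_vcd, exp_va, alpha, thermo, cfg, sim_cfg,
                         weights_fn) {
  keep_of <- function(sp) sp$measured & mask_keep(sim_cfg$mask, sp$grid)
  score_ctx <- function(sp, which) {
    keep <- keep_of(sp)
    if (sum(keep) < 2L) stopf("fewer than 2 grid points remain after masking")
    wq <- trap_weights(sp$grid, keep)
    g <- sp$values[keep]
    gg <- sum(wq * g * g)
    if (gg <= 0) stopf("zero-norm experimental %s spectrum", which)
    M <- broadened_matrix(ensemble, which, cfg)[keep, , drop = FALSE]
    list(M = M, wg = wq * g, wq = wq, gg = gg)
  }
  vcd <- score_ctx(exp_vcd, "VCD")
  va <- if (alpha > 0) {
    if (is.null(exp_va)) stopf("alpha > 0 requires an experimental VA spectrum")
    score_ctx(exp_va, "VA")
  } else NULL
  cos_pop <- function(ctx, W) {
    C <- ctx$M %*% W
    num <- as.vector(crossprod(C, ctx$wg))
    ff <- colSums(C * C * ctx$wq)
    s <- num / sqrt(pmax(ff, 1e-300) * ctx$gg)
    pmin(1, pmax(-1, s))
  }
  function(pop) {
    W <- weights_fn(pop)
    f <- cos_pop(vcd, W)
    if (!is.null(va)) f <- alpha * cos_pop(va, W) + (1 - alpha) * f
    f
  }
}

# Column-wise Boltzmann weights for a population of modulated energies.
pop_boltzmann <- function(energies, deltas_pop, kT) {
  X <- -(energies + deltas_pop) / kT
  X <- sweep(X, 2, apply(X, 2, max))
  W <- exp(X)
  sweep(W, 2, colSums(W), `/`)
}

#' Fit conformer energy modulations to an experimental VCD spectrum
#'
#' The central estimator: maximizes the VCD overlap (SimVCD) of the composite
#' ensemble spectrum over per-conformer energy modulations
#' `delta_i in [-demax, +demax]`, using a genetic algorithm.  `demax` encodes
#' the assumed uncertainty of the computed conformer energies (typically
#' 1-2 kcal/mol for DFT).  The plain Boltzmann solution (all deltas zero) is
#' seeded into the initial population, so the fitted overlap is never worse
#' than the unfitted one.
#'
#' @param ensemble a [vcd_ensemble()].
#' @param exp_vcd experimental VCD spectrum on the broadening grid.
#' @param exp_va optional experimental VA spectrum (reported alongside and
#'   used in the fitness when `alpha > 0`).
#' @param demax maximum energy modulation (kcal/mol), > 0.
#' @param thermo a [thermo_config()].
#' @param ga a [ga_config()].
#' @param sim_cfg a [similarity_config()].
#' @param cfg a [broadening_config()].
#' @param alpha weight of the VA overlap in the fitness,
#'   `alpha*SimVA + (1-alpha)*SimVCD`; default 0 (VCD only).
#' @param init_genomes optional matrix of warm-start genomes (one column per
#'   genome, clipped to bounds), appended to the seeded population.
#' @return an object of class `vcdfit`; see [summary.vcdfit()].
#' @seealso [vcdfit()] for the user-facing front door, [fit_free()] for the
#'   unconstrained variant.
#' @export
fit_energies <- function(ensemble, exp_vcd, exp_va = NULL, demax = 1,
                         thermo = thermo_config(), ga = ga_config(),
                         sim_cfg = similarity_config(),
                         cfg = broadening_config(), alpha = 0,
                         init_genomes = NULL) {
  if (!is_scalar_number(demax) || demax <= 0) stopf("demax must be > 0")
  n <- ensemble$n
  kT <- thermo$k_B * thermo$temperature
  if (n == 1L) {
    w <- 1
    sp <- sim_pair(ensemble, w, exp_va, exp_vcd, cfg, sim_cfg)
    return(new_vcdfit(ensemble, exp_vcd, exp_va, deltas = 0, weights = w,
                      sim_vcd = sp[["sim_vcd"]], sim_va = sp[["sim_va"]],
                      history = sp[["sim_vcd"]], demax = demax, free = FALSE,
                      thermo = thermo, cfg = cfg, sim_cfg = sim_cfg, ga = ga,
                      generations_run = 0L))
  }
  fitness <- make_fitness(ensemble, exp_vcd, exp_va, alpha, thermo, cfg,
                          sim_cfg, weights_fn = function(pop) {
                            pop_boltzmann(ensemble$energies, pop, kT)
                          })
  init <- cbind(rep(0, n), init_genomes)
  if (is.null(ga$mutation_sigma)) ga$mutation_sigma <- demax / 10
  res <- ga_optimize(n, -demax, demax, fitness, ga, init = init)
  w <- as.vector(pop_boltzmann(ensemble$energies, matrix(res$genome), kT))
  sp <- sim_pair(ensemble, w, exp_va, exp_vcd, cfg, sim_cfg)
  new_vcdfit(ensemble, exp_vcd, exp_va, deltas = res$genome, weights = w,
             sim_vcd = sp[["sim_vcd"]], sim_va = sp[["sim_va"]],
             history = res$history, demax = demax, free = FALSE,
             thermo = thermo, cfg = cfg, sim_cfg = sim_cfg, ga = ga,
             generations_run = res$generations_run)
}

#' Fit conformer weights freely (unbounded energy modulation)
#'
#' Optimizes the population weights directly on the probability simplex via
#' softmax-parameterized genes, so the result does not depend on the starting
#' energies at all.  Equivalent to [fit_energies()] with an effectively
#' unbounded `demax`.
#'
#' @inheritParams fit_energies
#' @return an object of class `vcdfit` with `free = TRUE`; reported deltas
#'   are the energy modulations implied by the fitted weights relative to
#'   the input energies.
#' @export
fit_free <- function(ensemble, exp_vcd, exp_va = NULL,
                     thermo = thermo_config(), ga = ga_config(),
                     sim_cfg = similarity_config(), cfg = broadening_config(),
                     alpha = 0, init_genomes = NULL) {
  n <- ensemble$n
  if (n < 2L) stopf("free fitting needs at least 2 conformers")
  kT <- thermo$k_B * thermo$temperature
  bound <- 10  # softmax genes in [-10, 10]: weight ratios up to e^20
  softmax_pop <- function(pop) {
    X <- sweep(pop, 2, apply(pop, 2, max))
    W <- exp(X)
    sweep(W, 2, colSums(W), `/`)
  }
  fitness <- make_fitness(ensemble, exp_vcd, exp_va, alpha, thermo, cfg,
                          sim_cfg, weights_fn = softmax_pop)
  # seed the Boltzmann solution of the input energies plus the uniform one
  bw_gene <- pmax(-bound, pmin(bound, -ensemble$energies / kT))
  init <- cbind(bw_gene, rep(0, n), init_genomes)
  if (is.null(ga$mutation_sigma)) ga$mutation_sigma <- 1
  res <- ga_optimize(n, -bound, bound, fitness, ga, init = init)
  w <- as.vector(softmax_pop(matrix(res$genome)))
  sp <- sim_pair(ensemble, w, exp_va, exp_vcd, cfg, sim_cfg)
  # energy modulations implied by the fitted weights (gauge: min modulated
  # energy = 0)
  e_fit <- -kT * log(pmax(w, 1e-300))
  e_fit <- e_fit - min(e_fit)
  new_vcdfit(ensemble, exp_vcd, exp_va, deltas = e_fit - ensemble$energies,
             weights = w, sim_vcd = sp[["sim_vcd"]], sim_va = sp[["sim_va"]],
             history = res$history, demax = Inf, free = TRUE, thermo = thermo,
             cfg = cfg, sim_cfg = sim_cfg, ga = ga,
             generations_run = res$generations_run)
}

#' Fit conformer populations to an experimental VCD spectrum
#'
#' Front door of the package: fits the experimental spectrum with a weighted
#' sum of the broadened conformer spectra, the weights deriving from conformer
#' energies allowed to deviate from their computed values by at most `demax`
#' kcal/mol (or freely, `free = TRUE`).
#'
#' @inheritParams fit_energies
#' @param free if `TRUE`, ignore the energy bound and optimize weights on the
#'   simplex directly.
#' @param ... passed on to [fit_energies()] or [fit_free()].
#' @return an object of class `vcdfit` with methods `print`, `summary`,
#'   `coef` (energy modulations), `weights`, `fitted`, `residuals`, `plot`
#'   and `simulate`.
#' @examples
#' syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 7))
#' exper <- generate_experiment(syn)
#' fit <- vcdfit(syn$ensemble, exper$vcd, exper$va, demax = 2,
#'               ga = ga_config(population_size = 32, generations = 40))
#' summary(fit)
#' @export
vcdfit <- function(ensemble, exp_vcd, exp_va = NULL, demax = 1, free = FALSE,
                   ...) {
  fit <- if (free) {
    fit_free(ensemble, exp_vcd, exp_va, ...)
  } else {
    fit_energies(ensemble, exp_vcd, exp_va, demax = demax, ...)
  }
  fit$call <- match.call()
  fit
}

new_vcdfit <- function(ensemble, exp_vcd, exp_va, deltas, weights, sim_vcd,
                       sim_va, history, demax, free, thermo, cfg, sim_cfg, ga,
                       generations_run) {
  modulated <- ensemble$energies + deltas
  structure(list(call = NULL, ensemble = ensemble, exp_vcd = exp_vcd,
                 exp_va = exp_va, deltas = deltas,
                 modulated_energies = modulated - min(modulated),
                 weights = weights, sim_vcd = sim_vcd, sim_va = sim_va,
                 history = history, demax = demax, free = free,
                 thermo = thermo, cfg = cfg, sim_cfg = sim_cfg, ga = ga,
                 generations_run = generations_run, seed = ga$seed),
            class = "vcdfit")
}

#' Overlap as a function of the conformer energy window
#'
#' Restricts the ensemble to conformers within each energy window and
#' computes the VCD overlap with the experiment using the arithmetic mean,
#' the Boltzmann weights, or GA-fitted weights.  Comparing the `mean` and
#' `bw` curves locates the window size at which the computed energies start
#' to carry information -- an empirical estimate of their uncertainty (see
#' [estimate_energy_uncertainty()]).
#'
#' @param ensemble a [vcd_ensemble()].
#' @param exp_vcd experimental VCD spectrum.
#' @param window_grid ascending energy windows (kcal/mol).
#' @param method `"mean"`, `"bw"` or `"fitted"`.
#' @param demax,thermo,ga,sim_cfg,cfg as in [fit_energies()].
#' @return data frame with columns `window`, `n_conformers`, `overlap`.
#' @export
overlap_vs_window <- function(ensemble, exp_vcd,
                              window_grid = seq(0.25, 3, by = 0.25),
                              method = c("bw", "mean", "fitted"), demax = 1,
                              thermo = thermo_config(), ga = ga_config(),
                              sim_cfg = similarity_config(),
                              cfg = broadening_config()) {
  method <- match.arg(method)
  if (is.unsorted(window_grid, strictly = TRUE)) {
    stopf("window_grid must be strictly ascending")
  }
  rows <- lapply(window_grid, function(w) {
    idx <- which(ensemble$energies <= w)
    if (length(idx) == 0L) stopf("energy window %g retains no conformer", w)
    sub <- subset_ensemble(ensemble, idx)
    ov <- switch(method,
      mean = sim_overlap(composite_spectrum(sub, arithmetic_weights(sub$n),
                                            "VCD", cfg), exp_vcd, sim_cfg),
      bw = sim_overlap(composite_spectrum(sub,
                                          boltzmann_weights(sub$energies, thermo),
                                          "VCD", cfg), exp_vcd, sim_cfg),
      fitted = {
        if (sub$n == 1L) {
          sim_overlap(composite_spectrum(sub, 1, "VCD", cfg), exp_vcd, sim_cfg)
        } else {
          fit_energies(sub, exp_vcd, demax = demax, thermo = thermo, ga = ga,
                       sim_cfg = sim_cfg, cfg = cfg)$sim_vcd
        }
      })
    data.frame(window = w, n_conformers = length(idx), overlap = ov)
  })
  do.call(rbind, rows)
}

# Sub-ensemble sharing stick data; energies re-shifted by the constructor
# (a pure gauge change for all weight models used here).
subset_ensemble <- function(ensemble, idx) {
  vcd_ensemble(ensemble$conformers[idx])
}

#' Mirror an ensemble (opposite enantiomer)
#'
#' The enantiomer has identical geometry-wise energies and VA spectra; every
#' rotational strength changes sign, so its VCD spectrum is the exact
#' negation.
#'
#' @param ensemble a [vcd_ensemble()].
#' @return the mirrored `vcd_ensemble`.
#' @export
mirror_ensemble <- function(ensemble) {
  vcd_ensemble(lapply(ensemble$conformers, function(cf) {
    conformer_record(cf$id, cf$energy,
                     stick_spectrum(cf$sticks$frequencies,
                                    cf$sticks$dipole_strengths,
                                    -cf$sticks$rotational_strengths))
  }))
}
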