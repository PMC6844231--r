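# Confidence machinery: k-fold cross-validation over spectral blocks,
# enantiomer discrimination, empirical energy-uncertainty estimation, and
# conformer-necessity refits.

# Cut the kept grid points into contiguous blocks of about `width` cm^-1.
# Adjacent points within a linewidth are almost perfectly correlated, so
# cross-validation folds are built from whole blocks (default 2*FWHM wide),
# never from individual points.
spectral_blocks <- function(grid, keep, width) {
  step <- grid[2L] - grid[1L]
  len <- max(2L, round(width / step))
  idx <- which(keep)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  blocks <- list()
  for (r in runs) {
    nb <- max(1L, floor(length(r) / len))
    cut <- rep(seq_len(nb), each = ceiling(length(r) / nb))[seq_along(r)]
    blocks <- c(blocks, split(r, cut))
  }
  unname(blocks)
}

#' k-fold cross-validation of an energy-modulation fit
#'
#' The masked spectral grid is cut into contiguous blocks two linewidths
#' wide; blocks are shuffled (seeded) and dealt round-robin into `k` folds.
#' For each fold the energy modulations are fitted on the training blocks
#' only and the overlap is evaluated on the held-out blocks.  A mean test
#' overlap well below the train overlap is the overfitting signature: the
#' fit is absorbing noise, not conformational information.
#'
#' @param ensemble a [vcd_ensemble()].
#' @param exp_vcd experimental VCD spectrum.
#' @param k number of folds (>= 2), default 5.
#' @param demax,thermo,ga,sim_cfg,cfg as in [fit_energies()].
#' @param seed seed for the fold assignment (the GA uses `ga$seed`).
#' @param combine `"per_fold"`: mean of per-fold test overlaps (default);
#'   `"pooled"`: one overlap of the concatenated per-fold predictions.
#' @return an object of class `vcd_cv` with per-fold train/test overlaps.
#' @export
kfold_cv <- function(ensemble, exp_vcd, k = 5, demax = 1,
                     thermo = thermo_config(), ga = ga_config(),
                     sim_cfg = similarity_config(), cfg = broadening_config(),
                     seed = 1, combine = c("per_fold", "pooled")) {
  combine <- match.arg(combine)
  if (!is_scalar_number(k) || k < 2) stopf("k must be >= 2")
  k <- as.integer(k)
  keep <- exp_vcd$measured & mask_keep(sim_cfg$mask, exp_vcd$grid)
  blocks <- spectral_blocks(exp_vcd$grid, keep, 2 * cfg$fwhm)
  if (length(blocks) < 2L * k) {
    stopf("only %d spectral blocks for %d folds; need at least %d",
          length(blocks), k, 2L * k)
  }
  perm <- with_seed(seed, sample.int(length(blocks)))
  fold_of <- rep_len(seq_len(k), length(blocks))[order(perm)]
  fold_train <- numeric(k); fold_test <- numeric(k)
  pooled_pred <- rep(NA_real_, length(exp_vcd$grid))
  for (f in seq_len(k)) {
    test_idx <- unlist(blocks[fold_of == f])
    train_meas <- exp_vcd$measured
    train_meas[test_idx] <- FALSE
    exp_train <- continuous_spectrum(exp_vcd$grid, exp_vcd$values,
                                     exp_vcd$mode, measured = train_meas)
    fit <- fit_energies(ensemble, exp_train, demax = demax, thermo = thermo,
                        ga = ga, sim_cfg = sim_cfg, cfg = cfg)
    fold_train[f] <- fit$sim_vcd
    calc <- fitted(fit, "VCD")
    test_meas <- rep(FALSE, length(exp_vcd$grid))
    test_meas[test_idx] <- TRUE
    exp_test <- continuous_spectrum(exp_vcd$grid, exp_vcd$values,
                                    exp_vcd$mode, measured = test_meas)
    fold_test[f] <- sim_overlap(calc, exp_test, sim_cfg)
    pooled_pred[test_idx] <- calc$values[test_idx]
  }
  mean_test <- if (combine == "per_fold") mean(fold_test) else {
    pred <- continuous_spectrum(exp_vcd$grid,
                                ifelse(is.na(pooled_pred), 0, pooled_pred),
                                "VCD", measured = !is.na(pooled_pred))
    sim_overlap(pred, exp_vcd, sim_cfg)
  }
  structure(list(k = k, fold_train = fold_train, fold_test = fold_test,
                 mean_train = mean(fold_train), mean_test = mean_test,
                 combine = combine, demax = demax, n_blocks = length(blocks),
                 seed = seed),
            class = "vcd_cv")
}

#' @export
print.vcd_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (demax = %g, %d spectral blocks)\n",
              x$k, x$demax, x$n_blocks))
  cat(sprintf("  mean train overlap: %.4f\n  mean test overlap:  %.4f (%s)\n",
              x$mean_train, x$mean_test, x$combine))
  invisible(x)
}

#' Cross-validated overlap versus number of conformers
#'
#' For each `n` in `n_grid`, runs [kfold_cv()] on the `n` lowest-energy
#' conformers and reports alongside the Boltzmann-weight overlap and the
#' fully-fitted overlap of the same subset.  A test-overlap column that
#' peaks at small `n` and then falls below the Boltzmann column signals
#' that the additional conformers are being used to fit noise.
#'
#' @inheritParams kfold_cv
#' @param n_grid conformer counts to evaluate (each within the ensemble size).
#' @return data frame with columns `n`, `test_overlap`, `train_overlap`,
#'   `bw_overlap`, `fitted_overlap`.
#' @export
cv_vs_nconf <- function(ensemble, exp_vcd, n_grid, k = 5, demax = 1,
                        thermo = thermo_config(), ga = ga_config(),
                        sim_cfg = similarity_config(),
                        cfg = broadening_config(), seed = 1) {
  if (any(n_grid < 1) || any(n_grid > ensemble$n)) {
    stopf("n_grid must lie within 1..%d", ensemble$n)
  }
  o <- order(ensemble$energies)
  rows <- lapply(n_grid, function(n) {
    sub <- subset_ensemble(ensemble, o[seq_len(n)])
    bw <- sim_overlap(composite_spectrum(sub, boltzmann_weights(sub$energies,
                                                                thermo),
                                         "VCD", cfg), exp_vcd, sim_cfg)
    if (n == 1L) {
      return(data.frame(n = n, test_overlap = bw, train_overlap = bw,
                        bw_overlap = bw, fitted_overlap = bw))
    }
    fit <- fit_energies(sub, exp_vcd, demax = demax, thermo = thermo, ga = ga,
                        sim_cfg = sim_cfg, cfg = cfg)
    cv <- kfold_cv(sub, exp_vcd, k = k, demax = demax, thermo = thermo,
                   ga = ga, sim_cfg = sim_cfg, cfg = cfg, seed = seed)
    data.frame(n = n, test_overlap = cv$mean_test,
               train_overlap = cv$mean_train, bw_overlap = bw,
               fitted_overlap = fit$sim_vcd)
  })
  do.call(rbind, rows)
}

#' Cross-validated overlap versus the energy-modulation bound
#'
#' Runs [kfold_cv()] for each value of `demax_grid` (same fold assignment
#' throughout).  The fully-fitted overlap column is computed with warm
#' starts along the grid, making it non-decreasing — the feasible sets are
#' nested.  Note that a small `demax` is not a recommended overfitting
#' control: fitted energies pile up at the bound and the weights are not
#' truly optimized.
#'
#' @inheritParams kfold_cv
#' @param demax_grid ascending positive energy-modulation bounds (kcal/mol).
#' @return data frame with columns `demax`, `test_overlap`, `train_overlap`,
#'   `fitted_overlap`.
#' @export
cv_vs_demax <- function(ensemble, exp_vcd, demax_grid, k = 5,
                        thermo = thermo_config(), ga = ga_config(),
                        sim_cfg = similarity_config(),
                        cfg = broadening_config(), seed = 1) {
  if (any(demax_grid <= 0) || is.unsorted(demax_grid, strictly = TRUE)) {
    stopf("demax_grid must be ascending and positive")
  }
  warm <- NULL
  rows <- lapply(demax_grid, function(dm) {
    fit <- fit_energies(ensemble, exp_vcd, demax = dm, thermo = thermo,
                        ga = ga, sim_cfg = sim_cfg, cfg = cfg,
                        init_genomes = warm)
    warm <<- matrix(fit$deltas)
    cv <- kfold_cv(ensemble, exp_vcd, k = k, demax = dm, thermo = thermo,
                   ga = ga, sim_cfg = sim_cfg, cfg = cfg, seed = seed)
    data.frame(demax = dm, test_overlap = cv$mean_test,
               train_overlap = cv$mean_train, fitted_overlap = fit$sim_vcd)
  })
  do.call(rbind, rows)
}

#' Two-enantiomer discrimination test
#'
#' Fits the experimental VCD spectrum with the ensemble as given and with
#' its mirror image (all rotational strengths negated — the opposite
#' enantiomer).  With enough conformers almost any spectrum can be fitted
#' to some extent, so the mirror overlap alone is not conclusive; the
#' assignment is trusted only when the overlap DIFFERENCE between the two
#' fits reaches the threshold (default 0.4).
#'
#' @inheritParams fit_energies
#' @param threshold minimum overlap difference for an "assigned" verdict.
#' @return an object of class `enantiomer_test` with fields `sim_correct`,
#'   `sim_mirror`, `delta`, `verdict` and the two fits.
#' @export
enantiomer_test <- function(ensemble, exp_vcd, demax = 1, exp_va = NULL,
                            thermo = thermo_config(), ga = ga_config(),
                            sim_cfg = similarity_config(),
                            cfg = broadening_config(), threshold = 0.4) {
  fit_c <- fit_energies(ensemble, exp_vcd, exp_va, demax = demax,
                        thermo = thermo, ga = ga, sim_cfg = sim_cfg, cfg = cfg)
  fit_m <- fit_energies(mirror_ensemble(ensemble), exp_vcd, exp_va,
                        demax = demax, thermo = thermo, ga = ga,
                        sim_cfg = sim_cfg, cfg = cfg)
  delta <- fit_c$sim_vcd - fit_m$sim_vcd
  structure(list(sim_correct = fit_c$sim_vcd, sim_mirror = fit_m$sim_vcd,
                 delta = delta,
                 verdict = if (delta >= threshold) "assigned" else "inconclusive",
                 threshold = threshold, fit_correct = fit_c, fit_mirror = fit_m),
            class = "enantiomer_test")
}

#' @export
print.enantiomer_test <- function(x, ...) {
  cat("Enantiomer discrimination test\n")
  cat(sprintf("  fit to given enantiomer:    SimVCD = %.4f\n", x$sim_correct))
  cat(sprintf("  fit to mirrored enantiomer: SimVCD = %.4f\n", x$sim_mirror))
  cat(sprintf("  difference = %.4f (threshold %.2f) -> %s\n",
              x$delta, x$threshold, x$verdict))
  invisible(x)
}

#' Empirical estimate of the conformer-energy uncertainty
#'
#' Compares, over a grid of energy windows, the VCD overlap of the
#' Boltzmann-weighted composite with that of the arithmetic-mean composite
#' of the same conformers.  As long as the window is smaller than the
#' energy error, the computed energies carry no information and the mean
#' does as well as (or better than) the Boltzmann weights; the window at
#' which the Boltzmann composite starts to win and keeps winning estimates
#' the energy uncertainty.
#'
#' @param ensemble a [vcd_ensemble()].
#' @param exp_vcd experimental VCD spectrum.
#' @param window_grid ascending energy windows (kcal/mol).
#' @param thermo a [thermo_config()].
#' @param sim_cfg a [similarity_config()].
#' @param cfg a [broadening_config()].
#' @return an object of class `energy_uncertainty`: `estimate` (kcal/mol,
#'   0 if the Boltzmann composite wins everywhere), `censored` (`TRUE` when
#'   the mean wins even at the largest window, so the estimate is only a
#'   lower bound), and the window table.
#' @export
estimate_energy_uncertainty <- function(ensemble, exp_vcd,
                                        window_grid = seq(0.25, 3, by = 0.25),
                                        thermo = thermo_config(),
                                        sim_cfg = similarity_config(),
                                        cfg = broadening_config()) {
  if (length(window_grid) == 0L) stopf("empty window grid")
  mean_tab <- overlap_vs_window(ensemble, exp_vcd, window_grid, "mean",
                                thermo = thermo, sim_cfg = sim_cfg, cfg = cfg)
  bw_tab <- overlap_vs_window(ensemble, exp_vcd, window_grid, "bw",
                              thermo = thermo, sim_cfg = sim_cfg, cfg = cfg)
  tab <- data.frame(window = window_grid, n_conformers = mean_tab$n_conformers,
                    mean_overlap = mean_tab$overlap,
                    bw_overlap = bw_tab$overlap)
  losing <- tab$bw_overlap < tab$mean_overlap
  if (!any(losing)) {
    est <- 0; censored <- FALSE
  } else if (losing[length(losing)]) {
    est <- max(window_grid); censored <- TRUE
  } else {
    est <- window_grid[max(which(losing)) + 1L]; censored <- FALSE
  }
  structure(list(estimate = est, censored = censored, table = tab),
            class = "energy_uncertainty")
}

#' @export
print.energy_uncertainty <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Estimated energy uncertainty: >= %g kcal/mol (mean beats BW over the whole window grid)\n",
                x$estimate))
  } else {
    cat(sprintf("Estimated energy uncertainty: %g kcal/mol\n", x$estimate))
  }
  invisible(x)
}

#' Is a particular conformer needed to explain the experiment?
#'
#' Fits the experiment with the full ensemble and with one conformer
#' removed (energies re-optimized from scratch).  A substantial drop in the
#' overlap indicates the conformer is genuinely present; a drop near zero
#' means the spectrum can be explained without it.
#'
#' @inheritParams fit_energies
#' @param conformer_id id of the conformer to remove.
#' @return list with `overlap_with`, `overlap_without`, `difference` and the
#'   two fits.
#' @export
conformer_necessity <- function(ensemble, exp_vcd, conformer_id, demax = 1,
                                thermo = thermo_config(), ga = ga_config(),
                                sim_cfg = similarity_config(),
                                cfg = broadening_config()) {
  if (ensemble$n < 2L) stopf("cannot remove a conformer from a singleton ensemble")
  i <- match(conformer_id, ensemble$ids)
  if (is.na(i)) stopf("unknown conformer id: %s", conformer_id)
  fit_full <- fit_energies(ensemble, exp_vcd, demax = demax, thermo = thermo,
                           ga = ga, sim_cfg = sim_cfg, cfg = cfg)
  reduced <- subset_ensemble(ensemble, setdiff(seq_len(ensemble$n), i))
  fit_red <- fit_energies(reduced, exp_vcd, demax = demax, thermo = thermo,
                          ga = ga, sim_cfg = sim_cfg, cfg = cfg)
  list(conformer_id = conformer_id, overlap_with = fit_full$sim_vcd,
       overlap_without = fit_red$sim_vcd,
       difference = fit_full$sim_vcd - fit_red$sim_vcd,
       fit_with = fit_full, fit_without = fit_red)
}
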