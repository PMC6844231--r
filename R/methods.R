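# S3 methods for "vcdfit" objects.

#' @export
print.vcdfit <- function(x, ...) {
  cat("Conformer-population fit to a VCD spectrum\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  kind <- if (x$free) "free weights (unbounded)" else
    sprintf("energy modulation, demax = %g kcal/mol", x$demax)
  cat(sprintf("  %d conformers, %s\n", x$ensemble$n, kind))
  cat(sprintf("  SimVCD = %.4f", x$sim_vcd))
  if (!is.na(x$sim_va)) cat(sprintf("   SimVA = %.4f", x$sim_va))
  cat(sprintf("   (%d GA generations)\n", x$generations_run))
  invisible(x)
}

#' Summary of a conformer-population fit
#'
#' Reports the final overlaps, the leading conformer populations with their
#' computed and fitted (modulated) relative energies, and flags pairs of
#' conformers whose VCD spectra are nearly collinear (a flat direction of
#' the fit: any weight split between such a pair gives the same fitness).
#'
#' @param object a `vcdfit` object.
#' @param n_top number of leading conformers to tabulate.
#' @param ... unused.
#' @return an object of class `summary.vcdfit`.
#' @export
summary.vcdfit <- function(object, n_top = 10, ...) {
  o <- order(object$weights, decreasing = TRUE)
  top <- utils::head(o, n_top)
  tab <- data.frame(id = object$ensemble$ids[top],
                    weight = object$weights[top],
                    energy = object$ensemble$energies[top],
                    delta = object$deltas[top],
                    fitted_energy = object$modulated_energies[top])
  flat <- NULL
  if (object$ensemble$n <= 120) {
    M <- broadened_matrix(object$ensemble, "VCD", object$cfg)
    cs <- sqrt(colSums(M^2))
    nz <- cs > 0
    Cn <- sweep(M[, nz, drop = FALSE], 2, cs[nz], `/`)
    cc <- crossprod(Cn)
    pairs <- which(cc > 0.9999 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      ids <- object$ensemble$ids[nz]
      flat <- data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]])
    }
  }
  structure(list(fit = object, top = tab, flat = flat), class = "summary.vcdfit")
}

#' @export
print.summary.vcdfit <- function(x, ...) {
  print(x$fit)
  cat("\nLeading conformer populations:\n")
  tab <- x$top
  tab$weight <- sprintf("%.4f", tab$weight)
  for (cn in c("energy", "delta", "fitted_energy")) {
    tab[[cn]] <- sprintf("%.3f", x$top[[cn]])
  }
  print(tab, row.names = FALSE)
  if (!is.null(x$flat)) {
    cat("\nNear-collinear VCD spectra (flat fit directions):\n")
    print(x$flat, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.vcdfit <- function(object, ...) {
  stats::setNames(object$deltas, object$ensemble$ids)
}

#' @export
weights.vcdfit <- function(object, ...) {
  stats::setNames(object$weights, object$ensemble$ids)
}

#' Fitted composite spectrum
#'
#' @param object a `vcdfit` object.
#' @param which `"VCD"` or `"VA"`.
#' @param ... unused.
#' @return a [continuous_spectrum()] at the fitted weights.
#' @export
fitted.vcdfit <- function(object, which = c("VCD", "VA"), ...) {
  which <- match.arg(which)
  composite_spectrum(object$ensemble, object$weights, which, object$cfg)
}

#' Residual spectrum (experiment minus fitted composite)
#'
#' @param object a `vcdfit` object.
#' @param which `"VCD"` or `"VA"`.
#' @param ... unused.
#' @return numeric vector on the grid; `NA` at unmeasured or masked points.
#' @export
residuals.vcdfit <- function(object, which = c("VCD", "VA"), ...) {
  which <- match.arg(which)
  exp_sp <- if (which == "VCD") object$exp_vcd else object$exp_va
  if (is.null(exp_sp)) stopf("no experimental %s spectrum in this fit", which)
  calc <- fitted(object, which)
  keep <- exp_sp$measured & mask_keep(object$sim_cfg$mask, exp_sp$grid)
  r <- exp_sp$values - calc$values
  r[!keep] <- NA_real_
  stats::setNames(r, exp_sp$grid)
}

#' Plot a conformer-population fit
#'
#' Two panels: the experimental versus fitted VCD spectrum, and the best
#' fitness per GA generation.
#'
#' @param x a `vcdfit` object.
#' @param ... passed to the spectrum panel's `matplot`.
#' @export
plot.vcdfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  calc <- fitted(x, "VCD")
  keep <- x$exp_vcd$measured
  graphics::matplot(x$exp_vcd$grid[keep],
                    cbind(x$exp_vcd$values[keep], calc$values[keep]),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = expression(wavenumber ~ (cm^-1)),
                    ylab = "VCD intensity",
                    main = sprintf("SimVCD = %.4f", x$sim_vcd), ...)
  graphics::legend("topright", c("experiment", "fit"), lty = 1,
                   col = c("black", "red"), bty = "n", cex = 0.8)
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "generation", ylab = "best SimVCD")
  invisible(x)
}

#' Simulate pseudo-experimental spectra from a fitted model
#'
#' Draws `nsim` noisy replicates of the composite spectrum at the fitted
#' weights, adding Gaussian baseline noise scaled to the maximum absolute
#' intensity — the same noise model as the synthetic-data generator.
#'
#' @param object a `vcdfit` object.
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param which `"VCD"` or `"VA"`.
#' @param noise_sd baseline noise as a fraction of `max(abs(values))`.
#' @param ... unused.
#' @return a list of [continuous_spectrum()] objects.
#' @export
simulate.vcdfit <- function(object, nsim = 1, seed = NULL,
                            which = c("VCD", "VA"), noise_sd = 0.02, ...) {
  which <- match.arg(which)
  base <- fitted(object, which)
  sdv <- noise_sd * max(abs(base$values))
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      continuous_spectrum(base$grid,
                          base$values + stats::rnorm(length(base$values), 0, sdv),
                          mode = which)
    })
  })
}
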