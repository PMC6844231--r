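# Boltzmann, arithmetic-mean and modulation-derived conformer weights, and
# the composite (population-weighted) ensemble spectrum.

#' Thermodynamic configuration
#'
#' Room temperature by default.  The Boltzmann constant is pinned to
#' 0.0019872041 kcal mol^-1 K^-1 so outputs are bit-reproducible.
#'
#' @param temperature temperature in K (> 0), default 298.15.
#' @return an object of class `thermo_config`.
#' @export
thermo_config <- function(temperature = 298.15) {
  if (!is_scalar_number(temperature) || temperature <= 0) {
    stopf("temperature must be > 0")
  }
  structure(list(temperature = temperature, k_B = 0.0019872041),
            class = "thermo_config")
}

#' Boltzmann population weights from relative energies
#'
#' \deqn{w_i = \frac{e^{-E_i/k_B T}}{\sum_j e^{-E_j/k_B T}}}
#' computed shift-stably (the minimum energy is subtracted first, which
#' leaves the weights unchanged but avoids underflow).
#'
#' @param energies relative conformer energies (kcal/mol), finite.
#' @param thermo a [thermo_config()].
#' @return numeric weight vector summing to 1.
#' @export
boltzmann_weights <- function(energies, thermo = thermo_config()) {
  if (length(energies) == 0L) stopf("empty energy list")
  if (any(!is.finite(energies))) stopf("energies must be finite")
  kT <- thermo$k_B * thermo$temperature
  e <- exp(-(energies - min(energies)) / kT)
  e / sum(e)
}

#' Equal (arithmetic-mean) weights
#'
#' The "wisdom of the crowd" baseline: every conformer gets weight 1/n, which
#' makes the composite spectrum the arithmetic mean of the conformer spectra.
#'
#' @param n number of conformers (>= 1).
#' @return numeric weight vector of `1/n` repeated `n` times.
#' @export
arithmetic_weights <- function(n) {
  if (!is_scalar_number(n) || n < 1) stopf("n must be >= 1")
  rep(1 / n, n)
}

#' Weights from modulated energies
#'
#' Boltzmann weights of `energies + deltas`, where each per-conformer energy
#' modulation delta_i is bounded by `|delta_i| <= demax`.  This is the weight
#' model the fit optimizes: the modulations absorb the uncertainty of the
#' computed energies.
#'
#' @param energies relative conformer energies (kcal/mol).
#' @param deltas per-conformer energy modulations (kcal/mol), same length.
#' @param demax bound on `|delta_i|` (kcal/mol); `Inf` skips the check.
#' @param thermo a [thermo_config()].
#' @return numeric weight vector summing to 1.
#' @export
modulated_weights <- function(energies, deltas, demax = Inf,
                              thermo = thermo_config()) {
  if (length(deltas) != length(energies)) {
    stopf("deltas length (%d) must match energies length (%d)",
          length(deltas), length(energies))
  }
  if (is.finite(demax) && any(abs(deltas) > demax + 1e-12)) {
    stopf("|delta| exceeds demax = %g", demax)
  }
  boltzmann_weights(energies + deltas, thermo)
}

check_weights <- function(weights, n) {
  if (length(weights) != n) {
    stopf("weight vector length (%d) must match ensemble size (%d)",
          length(weights), n)
  }
  if (any(weights < -1e-12)) stopf("weights must be non-negative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) stopf("weights must sum to 1 (got %.10g)", s)
  weights / s
}

# Matrix of broadened per-conformer spectra (grid points x conformers),
# cached on the ensemble so the GA inner loop is one matrix product.
broadened_matrix <- function(ensemble, which, cfg) {
  key <- sprintf("%s|%.10g|%.10g|%.10g|%.10g", which, cfg$fwhm, cfg$grid_lo,
                 cfg$grid_hi, cfg$grid_step)
  cached <- ensemble$cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- vapply(ensemble$conformers, function(cf) {
    broaden(cf$sticks, which, cfg)$values
  }, numeric(length(cfg$grid)))
  m <- matrix(m, nrow = length(cfg$grid))
  ensemble$cache[[key]] <- m
  m
}

#' Composite (population-weighted) ensemble spectrum
#'
#' Pointwise weighted sum of the broadened conformer spectra.  Broadened
#' per-conformer spectra are cached on the ensemble, so repeated calls with
#' new weights cost a single matrix-vector product.
#'
#' @param ensemble a [vcd_ensemble()].
#' @param weights weight vector over the ensemble.
#' @param which `"VA"` or `"VCD"`.
#' @param cfg a [broadening_config()].
#' @return a [continuous_spectrum()].
#' @export
composite_spectrum <- function(ensemble, weights, which = c("VCD", "VA"),
                               cfg = broadening_config()) {
  which <- match.arg(which)
  weights <- check_weights(weights, ensemble$n)
  m <- broadened_matrix(ensemble, which, cfg)
  continuous_spectrum(cfg$grid, as.vector(m %*% weights), mode = which)
}

#' Write conformer weights as delimited text, sorted by descending weight
#'
#' @param ensemble a [vcd_ensemble()].
#' @param weights weight vector over the ensemble.
#' @param path output file.
#' @export
write_weights <- function(ensemble, weights, path) {
  weights <- check_weights(weights, ensemble$n)
  o <- order(weights, decreasing = TRUE)
  utils::write.csv(data.frame(id = ensemble$ids[o], weight = weights[o]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
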