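# The SimVCD/SimVA overlap between a calculated composite spectrum and the
# experimental spectrum: a normalized inner product on the (masked) grid,
# ranging from -1 for an exactly opposite spectrum to +1 for a perfect match.

#' Similarity configuration
#'
#' The default variant is the cosine overlap
#' \deqn{Sim = \frac{\langle f, g\rangle}{\|f\|\,\|g\|}}
#' with trapezoid-weighted inner products over the (masked) grid; it is scale
#' invariant and antisymmetric under negation, so it spans exactly
#' \eqn{[-1, +1]}.  The `tanimoto` variant
#' \eqn{\langle f,g\rangle / (\|f\|^2 + \|g\|^2 - \langle f,g\rangle)}
#' additionally penalizes amplitude mismatch.
#'
#' @param variant `"cosine"` (default) or `"tanimoto"`.
#' @param mask optional [region_mask()] restricting the comparison.
#' @return an object of class `similarity_config`.
#' @export
similarity_config <- function(variant = c("cosine", "tanimoto"), mask = NULL) {
  variant <- match.arg(variant)
  if (!is.null(mask) && !inherits(mask, "region_mask")) {
    stopf("mask must be a region_mask or NULL")
  }
  structure(list(variant = variant, mask = mask), class = "similarity_config")
}

#' Spectral overlap between a calculated and an experimental spectrum
#'
#' Both spectra must live on the same grid.  Points excluded by the mask or
#' flagged unmeasured in either spectrum are dropped; the remaining points
#' are weighted by composite-trapezoid quadrature so each contiguous segment
#' contributes its integral.
#'
#' @param calc,exp [continuous_spectrum()] objects on a common grid.
#' @param cfg a [similarity_config()].
#' @return overlap in `[-1, 1]`; `+1` for identical shapes, `-1` (cosine)
#'   for exact negation.
#' @export
sim_overlap <- function(calc, exp, cfg = similarity_config()) {
  if (length(calc$grid) != length(exp$grid) ||
      max(abs(calc$grid - exp$grid)) > 1e-8) {
    stopf("spectra must share the same grid")
  }
  keep <- calc$measured & exp$measured & mask_keep(cfg$mask, calc$grid)
  if (sum(keep) < 2L) stopf("fewer than 2 grid points remain after masking")
  w <- trap_weights(calc$grid, keep)
  f <- calc$values[keep]; g <- exp$values[keep]
  fg <- sum(w * f * g); ff <- sum(w * f * f); gg <- sum(w * g * g)
  if (ff <= 0 || gg <= 0) {
    stopf("zero-norm spectrum: overlap undefined (all-zero %s region?)",
          calc$mode)
  }
  s <- switch(cfg$variant,
              cosine = fg / sqrt(ff * gg),
              tanimoto = fg / (ff + gg - fg))
  min(1, max(-1, s))
}

#' VA and VCD overlaps from one weight vector
#'
#' Convenience wrapper: builds the composite VA and VCD spectra at the given
#' weights and returns both overlaps.
#'
#' @param ensemble a [vcd_ensemble()].
#' @param weights weight vector over the ensemble.
#' @param exp_va,exp_vcd experimental spectra (either may be `NULL`, in which
#'   case the corresponding overlap is `NA`).
#' @param cfg a [broadening_config()].
#' @param sim_cfg a [similarity_config()].
#' @return named numeric `c(sim_va = ..., sim_vcd = ...)`.
#' @export
sim_pair <- function(ensemble, weights, exp_va = NULL, exp_vcd = NULL,
                     cfg = broadening_config(), sim_cfg = similarity_config()) {
  sva <- if (is.null(exp_va)) NA_real_ else {
    sim_overlap(composite_spectrum(ensemble, weights, "VA", cfg), exp_va, sim_cfg)
  }
  svcd <- if (is.null(exp_vcd)) NA_real_ else {
    sim_overlap(composite_spectrum(ensemble, weights, "VCD", cfg), exp_vcd, sim_cfg)
  }
  c(sim_va = sva, sim_vcd = svcd)
}
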