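#' Stick spectrum of a single conformer
#'
#' A stick spectrum is the raw output of a vibrational frequency calculation:
#' one wavenumber per normal mode together with its dipole strength (the VA
#' intensity, non-negative) and rotational strength (the VCD intensity,
#' signed).  Units are arbitrary but must be consistent across the conformers
#' of an ensemble; the overlap measure used downstream is scale invariant.
#'
#' @param frequencies numeric vector of mode wavenumbers (cm^-1), all > 0.
#' @param dipole_strengths numeric vector of VA intensities, all >= 0.
#' @param rotational_strengths numeric vector of signed VCD intensities.
#' @return an object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(frequencies, dipole_strengths, rotational_strengths) {
  frequencies <- as.numeric(frequencies)
  dipole_strengths <- as.numeric(dipole_strengths)
  rotational_strengths <- as.numeric(rotational_strengths)
  n <- length(frequencies)
  if (length(dipole_strengths) != n || length(rotational_strengths) != n) {
    stopf("stick spectrum fields must have equal length (got %d, %d, %d)",
          n, length(dipole_strengths), length(rotational_strengths))
  }
  if (n > 0L) {
    if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
      stopf("mode frequencies must be finite and strictly positive")
    }
    if (any(!is.finite(dipole_strengths)) || any(dipole_strengths < 0)) {
      stopf("dipole strengths must be finite and non-negative")
    }
    if (any(!is.finite(rotational_strengths))) {
      stopf("rotational strengths must be finite")
    }
  }
  structure(list(frequencies = frequencies,
                 dipole_strengths = dipole_strengths,
                 rotational_strengths = rotational_strengths),
            class = "stick_spectrum")
}

#' One conformer: identifier, relative energy and stick spectrum
#'
#' @param id unique character label within an ensemble.
#' @param energy relative energy in kcal/mol (finite).
#' @param sticks a [stick_spectrum()].
#' @return an object of class `conformer_record`.
#' @export
conformer_record <- function(id, energy, sticks) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stopf("conformer id must be a non-empty string")
  }
  if (!is_scalar_number(energy)) stopf("conformer energy must be a finite number")
  if (!inherits(sticks, "stick_spectrum")) stopf("sticks must be a stick_spectrum")
  structure(list(id = id, energy = as.numeric(energy), sticks = sticks),
            class = "conformer_record")
}

#' Conformer ensemble
#'
#' Collects conformer records, shifts energies so the minimum is zero, and
#' attaches a cache for broadened per-conformer spectra so that repeated
#' composite evaluations (the inner loop of the genetic algorithm) cost a
#' single weighted sum.
#'
#' @param conformers list of [conformer_record()] objects with unique ids.
#' @return an object of class `vcd_ensemble` with fields `conformers`, `ids`,
#'   `energies` (min-shifted) and `n`.
#' @export
vcd_ensemble <- function(conformers) {
  if (length(conformers) < 1L) stopf("an ensemble needs at least one conformer")
  ok <- vapply(conformers, inherits, logical(1), what = "conformer_record")
  if (!all(ok)) stopf("all elements must be conformer_record objects")
  ids <- vapply(conformers, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stopf("duplicate conformer id: %s", ids[duplicated(ids)][1L])
  }
  energies <- vapply(conformers, `[[`, numeric(1), "energy")
  energies <- energies - min(energies)
  for (i in seq_along(conformers)) conformers[[i]]$energy <- energies[i]
  structure(list(conformers = conformers, ids = ids, energies = energies,
                 n = length(conformers), cache = new.env(parent = emptyenv())),
            class = "vcd_ensemble")
}

#' @export
print.vcd_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble: %d conformers, relative energies 0-%.3f kcal/mol\n",
              x$n, max(x$energies)))
  nm <- vapply(x$conformers, function(cf) length(cf$sticks$frequencies), integer(1))
  cat(sprintf("  modes per conformer: %d-%d\n", min(nm), max(nm)))
  invisible(x)
}

#' Line-broadening and grid configuration
#'
#' The grid and Lorentzian width on which stick spectra are turned into
#' continuous spectra.  The default full width at half maximum of 8 cm^-1 is
#' the conventional linewidth for solution-phase mid-IR VCD simulations; the
#' default grid covers the fingerprint region 900-1700 cm^-1 at 1 cm^-1.
#'
#' @param fwhm Lorentzian full width at half maximum Gamma (cm^-1), > 0.
#' @param grid_lo,grid_hi grid limits (cm^-1).
#' @param grid_step grid spacing (cm^-1); must satisfy `grid_step <= fwhm/4`
#'   so the line shape is adequately sampled.
#' @return an object of class `broadening_config` carrying the grid.
#' @export
broadening_config <- function(fwhm = 8, grid_lo = 900, grid_hi = 1700,
                              grid_step = 1) {
  if (!is_scalar_number(fwhm) || fwhm <= 0) stopf("fwhm must be > 0")
  if (grid_hi <= grid_lo) stopf("grid_hi must exceed grid_lo")
  if (!is_scalar_number(grid_step) || grid_step <= 0) stopf("grid_step must be > 0")
  if (grid_step > fwhm / 4) {
    stopf("grid_step (%g) must be <= fwhm/4 (%g) to sample the line shape",
          grid_step, fwhm / 4)
  }
  grid <- seq(grid_lo, grid_hi, by = grid_step)
  structure(list(fwhm = fwhm, grid_lo = grid_lo, grid_hi = grid_hi,
                 grid_step = grid_step, grid = grid),
            class = "broadening_config")
}

#' Continuous spectrum on a uniform wavenumber grid
#'
#' @param grid uniform, strictly ascending wavenumber grid (cm^-1).
#' @param values intensities, one per grid point.
#' @param mode `"VA"` or `"VCD"`.
#' @param measured optional logical vector marking grid points inside the
#'   experimentally measured range; unmeasured points are excluded from
#'   similarity evaluation automatically.
#' @return an object of class `vcd_spectrum`.
#' @export
continuous_spectrum <- function(grid, values, mode = c("VCD", "VA"),
                                measured = NULL) {
  mode <- match.arg(mode)
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values)) stopf("grid and values lengths differ")
  if (length(grid) < 2L) stopf("a spectrum needs at least 2 grid points")
  d <- diff(grid)
  if (any(d <= 0)) stopf("grid must be strictly ascending")
  if (max(d) - min(d) > 1e-8 * max(d)) stopf("grid must be uniform")
  if (any(!is.finite(values))) stopf("spectrum values must be finite")
  if (is.null(measured)) measured <- rep(TRUE, length(grid))
  if (length(measured) != length(grid)) stopf("measured flag length mismatch")
  structure(list(grid = grid, values = values, mode = mode,
                 measured = as.logical(measured)),
            class = "vcd_spectrum")
}

#' @export
print.vcd_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points, %.6g-%.6g cm^-1 (step %.6g)\n",
              x$mode, length(x$grid), min(x$grid), max(x$grid),
              x$grid[2] - x$grid[1]))
  if (!all(x$measured)) {
    cat(sprintf("  %d grid points flagged unmeasured\n", sum(!x$measured)))
  }
  invisible(x)
}

#' @export
plot.vcd_spectrum <- function(x, ...) {
  graphics::plot(x$grid, x$values, type = "l",
                 xlab = expression(wavenumber ~ (cm^-1)),
                 ylab = paste(x$mode, "intensity"), ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Region mask: wavenumber intervals included in similarity evaluation
#'
#' Intervals are half-open `[lo, hi)`, must not overlap, and denote the
#' INCLUDED regions.  Use [exclude_region()] to build the complement of an
#' excluded band (for instance dropping 1200-1400 cm^-1 from a comparison).
#'
#' @param intervals numeric matrix or two-column data frame of `[lo, hi)`
#'   rows, or a numeric vector of length 2 for a single interval.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(intervals) {
  if (is.numeric(intervals) && is.null(dim(intervals))) {
    if (length(intervals) != 2L) stopf("a single interval needs lo and hi")
    intervals <- matrix(intervals, ncol = 2L)
  }
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) stopf("intervals must have two columns (lo, hi)")
  if (any(intervals[, 1] >= intervals[, 2])) stopf("each interval needs lo < hi")
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1L &&
      any(intervals[-1L, 1] < intervals[-nrow(intervals), 2])) {
    stopf("mask intervals must not overlap")
  }
  structure(list(intervals = intervals), class = "region_mask")
}

#' Build a mask that excludes the given intervals from a full range
#'
#' @param lo,hi full wavenumber range of interest (cm^-1).
#' @param exclude matrix/vector of `[lo, hi)` intervals to exclude.
#' @return a [region_mask()] covering `[lo, hi)` minus the excluded bands.
#' @export
exclude_region <- function(lo, hi, exclude) {
  excl <- region_mask(exclude)$intervals
  keep <- list()
  cur <- lo
  for (i in seq_len(nrow(excl))) {
    a <- max(lo, excl[i, 1]); b <- min(hi, excl[i, 2])
    if (b <= cur) next
    if (a > cur) keep[[length(keep) + 1L]] <- c(cur, a)
    cur <- max(cur, b)
  }
  if (cur < hi) keep[[length(keep) + 1L]] <- c(cur, hi)
  if (length(keep) == 0L) stopf("exclusion removes the entire range")
  region_mask(do.call(rbind, keep))
}

# Logical inclusion vector of a mask over a grid.  hi + step/2 guards the
# half-open convention against floating-point grid arithmetic.
mask_keep <- function(mask, grid) {
  if (is.null(mask)) return(rep(TRUE, length(grid)))
  keep <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(mask$intervals))) {
    keep <- keep | (grid >= mask$intervals[i, 1] & grid < mask$intervals[i, 2])
  }
  keep
}

#' Restrict a spectrum to the grid points of a region mask
#'
#' @param spectrum a [continuous_spectrum()].
#' @param mask a [region_mask()]; must cover at least one grid point.
#' @return a `vcd_spectrum` containing only the included grid points (its
#'   grid may therefore be non-contiguous; an attribute `"step"` preserves
#'   the original spacing for quadrature).
#' @export
apply_mask <- function(spectrum, mask) {
  keep <- mask_keep(mask, spectrum$grid)
  if (!any(keep)) stopf("mask covers no grid point")
  out <- structure(list(grid = spectrum$grid[keep],
                        values = spectrum$values[keep],
                        mode = spectrum$mode,
                        measured = spectrum$measured[keep]),
                   class = "vcd_spectrum")
  attr(out, "step") <- spectrum$grid[2L] - spectrum$grid[1L]
  out
}

#' Lorentzian broadening of a stick spectrum
#'
#' Each mode contributes a unit-area Lorentzian centred at its wavenumber and
#' scaled by its strength, so the integral of the broadened spectrum over a
#' sufficiently wide grid equals the sum of the strengths:
#' \deqn{I(\nu) = \sum_k s_k \frac{\Gamma/2\pi}{(\nu-\nu_k)^2 + (\Gamma/2)^2}}
#'
#' @param sticks a [stick_spectrum()].
#' @param which `"VA"` (dipole strengths) or `"VCD"` (rotational strengths).
#' @param cfg a [broadening_config()].
#' @return a [continuous_spectrum()] on `cfg$grid`.
#' @export
broaden <- function(sticks, which = c("VCD", "VA"), cfg = broadening_config()) {
  which <- match.arg(which)
  s <- if (which == "VA") sticks$dipole_strengths else sticks$rotational_strengths
  continuous_spectrum(cfg$grid, lorentzian_sum(cfg$grid, sticks$frequencies, s,
                                               cfg$fwhm), mode = which)
}

lorentzian_sum <- function(grid, freqs, strengths, fwhm) {
  if (length(freqs) == 0L) return(numeric(length(grid)))
  hw <- fwhm / 2
  amp <- fwhm / (2 * pi)
  dev2 <- outer(grid, freqs, `-`)^2
  as.vector((amp / (dev2 + hw^2)) %*% strengths)
}

#' Scale the mode frequencies of a stick spectrum
#'
#' A single global multiplicative scaling factor compensating for the
#' systematic error of harmonic DFT frequencies; strengths are untouched.
#'
#' @param sticks a [stick_spectrum()].
#' @param factor dimensionless factor in `[0.9, 1.1]`.
#' @return the scaled `stick_spectrum`.
#' @export
scale_frequencies <- function(sticks, factor) {
  if (!is_scalar_number(factor) || factor < 0.9 || factor > 1.1) {
    stopf("scaling factor must lie in [0.9, 1.1], got %g", factor)
  }
  stick_spectrum(sticks$frequencies * factor, sticks$dipole_strengths,
                 sticks$rotational_strengths)
}

#' Apply a global frequency scaling factor to every conformer of an ensemble
#'
#' @param ensemble a [vcd_ensemble()].
#' @param factor dimensionless factor in `[0.9, 1.1]`.
#' @return a new `vcd_ensemble` (the broadened-spectrum cache is reset).
#' @export
scale_ensemble <- function(ensemble, factor) {
  vcd_ensemble(lapply(ensemble$conformers, function(cf) {
    conformer_record(cf$id, cf$energy, scale_frequencies(cf$sticks, factor))
  }))
}

#' Optimize the global frequency scaling factor against an experimental VA
#' spectrum
#'
#' Scans a grid of multiplicative scaling factors and returns the one that
#' maximizes the VA overlap between the weighted, broadened ensemble spectrum
#' and the experimental VA spectrum.  Ties are broken toward the factor
#' nearest 1 (no scaling preferred when the data cannot distinguish).
#'
#' @param ensemble a [vcd_ensemble()].
#' @param weights weight vector over the ensemble (see [boltzmann_weights()]).
#' @param exp_va experimental VA spectrum on the configured grid.
#' @param bounds length-2 numeric within `[0.9, 1.1]`.
#' @param step scan step (default 0.001).
#' @param cfg a [broadening_config()].
#' @param sim_cfg a [similarity_config()].
#' @return the optimal factor (scalar).
#' @export
optimize_scaling <- function(ensemble, weights, exp_va,
                             bounds = c(0.97, 1.03), step = 0.001,
                             cfg = broadening_config(),
                             sim_cfg = similarity_config()) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) stopf("invalid bounds")
  if (bounds[1] < 0.9 || bounds[2] > 1.1) stopf("bounds must lie within [0.9, 1.1]")
  if (exp_va$mode != "VA") stopf("optimize_scaling requires a VA spectrum")
  weights <- check_weights(weights, ensemble$n)
  # broadening is linear, so the weighted composite equals the broadening of
  # the pooled stick list with strengths premultiplied by the weights
  freqs <- unlist(lapply(ensemble$conformers, function(cf) cf$sticks$frequencies))
  s <- unlist(lapply(seq_len(ensemble$n), function(i) {
    ensemble$conformers[[i]]$sticks$dipole_strengths * weights[i]
  }))
  if (all(s == 0)) stopf("ensemble VA spectrum is identically zero")
  factors <- seq(bounds[1], bounds[2], by = step)
  ov <- vapply(factors, function(f) {
    calc <- continuous_spectrum(cfg$grid,
                                lorentzian_sum(cfg$grid, freqs * f, s, cfg$fwhm),
                                mode = "VA")
    sim_overlap(calc, exp_va, sim_cfg)
  }, numeric(1))
  best <- max(ov)
  cand <- factors[ov >= best - 1e-12]
  cand[which.min(abs(cand - 1))]
}
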