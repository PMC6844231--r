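---
title: "Fitting conformer populations to VCD spectra under energy uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting conformer populations to VCD spectra under energy uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcdfit)
```

## The model

A flexible chiral molecule populates many conformers at room temperature.
Its observed vibrational absorption (VA) and vibrational circular dichroism
(VCD) spectra are population-weighted sums of the single-conformer spectra.
Quantum chemistry supplies, per conformer $i$, a relative energy $E_i$
(kcal/mol) and a stick spectrum: mode frequencies $\nu_{ik}$, dipole
strengths $D_{ik} \ge 0$ (VA) and signed rotational strengths $R_{ik}$
(VCD).  Sticks are broadened with unit-area Lorentzians of full width at
half maximum $\Gamma$ (default 8 cm$^{-1}$, the conventional solution-phase
linewidth):

$$ f_i(\nu) = \sum_k s_{ik}\,
   \frac{\Gamma/2\pi}{(\nu - \nu_{ik})^2 + (\Gamma/2)^2}. $$

The textbook composite uses Boltzmann weights
$w_i \propto e^{-E_i/k_BT}$ at $T = 298.15$ K
($k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$, pinned to make outputs
bit-reproducible).  But DFT conformer energies carry errors of order 1–2
kcal/mol while $k_BT \approx 0.59$ kcal/mol, so the weights — and with them
the sign pattern of the composite VCD spectrum — are unreliable.  The
package's estimator therefore treats the energies as uncertain: it fits

$$ w_i(\delta) \propto \exp\!\big(-(E_i + \delta_i)/k_BT\big),
   \qquad |\delta_i| \le \Delta E^{\max}, $$

maximizing the overlap between the composite VCD spectrum and the
experiment.  $\Delta E^{\max}$ is the user's statement of how much they
distrust the computed energies; 1–2 kcal/mol is the realistic range.  A
free-fit variant (`fit_free()`) drops the bound entirely and optimizes the
weights on the probability simplex through softmax-parameterized genes, so
its result is independent of the starting energies; it answers "what is the
best this ensemble could ever do," at the price of abandoning the energies
as a prior.

## The similarity measure

Overlaps are cosine similarities with trapezoid-weighted inner products on
the wavenumber grid,

$$ \mathrm{Sim} = \frac{\langle f, g\rangle}{\lVert f\rVert\,
   \lVert g\rVert} \in [-1, +1], $$

which is $+1$ exactly for proportional spectra and $-1$ for a negated one
(the mirror enantiomer), and is invariant to overall intensity scaling — so
no absolute intensity calibration between theory and experiment is needed.
A Tanimoto variant,
$\langle f,g\rangle/(\lVert f\rVert^2 + \lVert g\rVert^2 -
\langle f,g\rangle)$, is available for users who want amplitude mismatch
penalized; all reported numbers in this package default to the cosine form.
Region masks restrict the inner product to chemically trustworthy intervals
(half-open $[lo, hi)$, e.g. excluding 1200–1400 cm$^{-1}$ where structural
dynamics invalidate static calculations), and grid points outside the
experimentally measured range are excluded automatically.

The default grid is 900–1700 cm$^{-1}$ in 1 cm$^{-1}$ steps — the mid-IR
fingerprint region — and the constructor enforces
`grid_step` $\le \Gamma/4$ so the line shape is sampled adequately.

## Frequency scaling

Harmonic DFT frequencies are systematically off by a percent or so.
`optimize_scaling()` applies a single global multiplicative factor, chosen
by grid search (step 0.001, bounds within $[0.9, 1.1]$) to maximize the VA
overlap; ties break toward 1 (no scaling) so the procedure never invents a
shift the data cannot support.  The VA spectrum is used because it is
sign-free and far less sensitive to the weights than the VCD spectrum.  A
per-interval piecewise variant was considered and rejected for the default:
with typical mid-IR data it adds free parameters faster than information.
Theory is always scaled toward experiment; the experiment is never rescaled.

## The genetic algorithm

The genome is $(\delta_1 \dots \delta_N)$, clipped to
$[-\Delta E^{\max}, +\Delta E^{\max}]$.  Defaults: population 128,
up to 300 generations, tournament selection (size 3), uniform crossover
(rate 0.7), per-gene Gaussian mutation (rate 0.2,
$\sigma = \Delta E^{\max}/10$), elitism 2, early stop when the best fitness
improves by less than $10^{-6}$ over 50 generations.  Three choices matter
more than the hyperparameters:

* **The Boltzmann genome is always seeded** ($\delta = 0$).  With elitism
  this guarantees the fitted overlap never falls below the plain
  Boltzmann-weight overlap — the fit can only add information.
* **Warm starts across $\Delta E^{\max}$ grids.** The feasible sets are
  nested, so the best overlap must be non-decreasing in
  $\Delta E^{\max}$; seeding each fit with the previous bound's best genome
  (as `cv_vs_demax()` does) makes the implementation honor this exactly
  instead of only up to GA noise.
* **Tie-breaking toward small $\lVert\delta\rVert_2$.** Among equal-fitness
  genomes the one closest to the computed energies is reported
  (maximum-parsimony deviation); a uniform shift of all $\delta_i$ is a pure
  gauge freedom (the weights are shift-invariant), so fitted energies are
  reported re-centred with their minimum at 0 while the raw bounded
  $\delta_i$ are kept in `coef()`.

Fitness is the VCD overlap alone by default; a mixed
$\alpha\,\mathrm{Sim_{VA}} + (1-\alpha)\,\mathrm{Sim_{VCD}}$ fitness is
available since VA data constrain the weights too, but VA spectra of
conformers are typically so similar that $\alpha > 0$ mostly dilutes the
signal.  Whole populations are scored with one matrix product per
generation (broadened conformer spectra are cached on the ensemble), so a
60-conformer fit takes a few seconds.

Everything stochastic takes a seed and is bit-reproducible; two fits with
equal seeds and inputs are identical.

## Cross-validation

Fitted weights can chase noise: the number of independent features in a
measured VCD spectrum is far smaller than 60 or 160 conformers.
`kfold_cv()` cuts the (masked) grid into contiguous blocks $2\Gamma$ wide
(16 cm$^{-1}$), shuffles them with a seed, deals them round-robin into $k$
folds (default 5), fits on the training blocks and evaluates on the
held-out blocks.  Blocks rather than points are essential: adjacent grid
points within a linewidth are nearly perfectly correlated, and point-wise
folds would leak the test set into training.  The summary is the mean of
per-fold test overlaps; an overlap of concatenated test predictions is
available as `combine = "pooled"`.

Two companion scans reproduce the standard diagnostics: `cv_vs_nconf()`
(test overlap versus the number of lowest-energy conformers admitted —
a decline flags that additional conformers fit noise) and `cv_vs_demax()`
(test overlap versus the bound — it typically rises and then falls, but a
small $\Delta E^{\max}$ is *not* a recommended overfitting control, because
fitted energies pile up at the bound and the weights are not truly
optimized; the cross-validated optimum is a diagnostic, not a
recommendation).

## Enantiomer discrimination

Since the mirror enantiomer has the identical VA spectrum and the exactly
negated VCD spectrum, `enantiomer_test()` refits the experiment with all
rotational strengths negated.  With enough conformers carrying
opposite-signed bands, the wrong enantiomer can fit surprisingly well — above
the traditional 0.4 single-spectrum threshold — so the verdict rests on the
overlap *difference* between the two fits (default threshold 0.4,
configurable).  `mirror_ensemble()` exposes the construction; mirroring the
ensemble swaps the two reported overlaps exactly.

## Estimating the energy uncertainty

`estimate_energy_uncertainty()` compares, over a grid of energy windows
(default 0.25–3 kcal/mol in 0.25 steps), the overlap of the
Boltzmann-weighted composite of conformers inside the window with that of
their arithmetic mean.  The reasoning: as long as the window is smaller than
the energy error, the computed ordering inside it is noise and equal weights
do just as well; once the window clearly exceeds the error, down-weighting
the top of the window pays off.  The smallest window from which the
Boltzmann curve stays at or above the mean curve is returned; 0 means the
energies dominate everywhere, and if the mean wins even at the largest
window the estimate is returned as that bound with a censoring flag.

A candid limitation found while validating this estimator on synthetic
ensembles: when the true thermal population is spread over many conformers
(energy spacings well below $k_BT$) and the energy errors are independent
per conformer, the arithmetic mean is close to optimal and the crossover
can lie beyond any practical window — the estimator then reports a censored
value rather than the corruption magnitude.  It recovers the magnitude
reliably only when the true population is concentrated on a few conformers.
Real DFT errors are partly systematic (rank-preserving) rather than
independent, which is friendlier to the estimator than the synthetic
worst case; treat censored estimates as "at least this much".

## The synthetic-data generator

`generate_ensemble()`/`generate_experiment()` create ensembles with known
ground truth so every claim above can be tested.  What is emulated, with
defaults:

* mode frequencies uniform on 950–1650 cm$^{-1}$, 30 modes per conformer;
  dipole strengths log-normal ($\mu = 0$, $\sigma = 0.8$); rotational
  strengths zero-mean normal with $\sigma$ equal to 5% of the mean dipole
  strength;
* **opposing signs**: a fraction (default 0.3) of modes is shared across
  conformers — same frequency and magnitude, random VCD sign per conformer —
  the feature that makes conformer weighting consequential;
* true energies exponential with mean 1 kcal/mol; *reported* energies carry
  i.i.d. Gaussian error (default $\sigma = 1$, the DFT rule of thumb);
* the theory handed to the fit differs from the truth the experiment is
  built from: stick frequencies perturbed by $\sigma = 3$ cm$^{-1}$
  (sub-linewidth), optionally rotational strengths perturbed too
  (`rot_error_sd`, default 0), mimicking DFT intensity errors;
* the pseudo-experiment is the true-weight composite of the *true* sticks
  plus Gaussian baseline noise (default 2% of the maximum intensity).

Passing tests on these data shows the estimator recovers populations when
its error model brackets reality; it does not certify behavior under error
sources the generator lacks (correlated energy errors, solvent band shapes,
baseline drifts, anharmonicity).

Two canonical fixtures are constructed rather than drawn, because their
defining property is structural:

* `generate_overfit_ensemble()`: 5 informative conformers on a 0–1.2
  kcal/mol ladder plus 55 redundant ones at 3.2–5.7 kcal/mol (true weights
  < 0.01), reported energies corrupted with $\sigma = 1$, baseline noise
  10%, and `rot_error_sd = 0.5`.  The intensity errors create mode-local
  misfit that redundant conformers can patch on any particular stretch of
  spectrum — precisely the non-generalizing flexibility cross-validation
  must expose.  With error-free intensities the model is nearly
  well-specified and there is no overfitting to detect.
* `generate_enantiomer_ensemble()`: 5 populated conformers plus partial
  mirrors whose rotational strengths are flipped on the modes carrying
  $q = 0.7$ of the VCD power (VA identical).  The wrong-enantiomer fit then
  has a controlled ceiling near $2q - 1$: it clears the naive 0.4 threshold
  while the overlap difference still discriminates — the situation the
  difference-based verdict exists for.  A random sign-opposition draw makes
  this property a per-seed coin flip, which is why it is built in.

## Numerical choices and degenerate inputs

* Quadrature: composite trapezoid per contiguous (masked) segment; isolated
  points degenerate to rectangles.
* Zero-norm spectra (e.g. an all-zero VCD region after masking) are an
  error, not a silent 0 — the comparison is undefined.
* Two conformers with identical spectra are a flat direction of the fit:
  any weight split gives identical fitness.  This is reported by
  `summary()` (spectral cosine > 0.9999), not treated as an error.
* Energies are min-shifted on ensemble construction; all weight models are
  invariant under uniform shifts, so this is presentation only.
* Overlaps are printed to 4 decimals, energies to 3.

## Problem sizes in the shipped tests

The suite exercises ensembles of 2–60 conformers on the default 801-point
grid, with GA populations of 16–96 and up to 300 generations; the
cross-validation and discrimination demonstrations run on the two
constructed fixtures above, and the uncertainty-estimator study uses 20
replicates of 40-conformer ensembles per corruption level.  These sizes
keep the whole suite to a few minutes while leaving every qualitative
regime (exact recovery, overfitting, censoring) represented.

## Known limitations

* No free-energy corrections: energies are whatever the user's quantum
  chemistry provides.
* Frequency scaling is a single global factor by default.
* JCAMP-DX support covers the uncompressed `XYDATA (X++(Y..Y))` and
  `XYPOINTS` dialects only.
* The uncertainty estimator's censoring behavior above.
* No gradient-based or Bayesian alternative to the GA; uncertainties on
  individual weights come only from cross-validation.
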