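# Synthetic conformer ensembles and pseudo-experimental spectra with known
# ground truth.  The generator emulates the statistical structure the
# fitting method assumes: conformers with partially shared bands whose VCD
# signs oppose, thermal (Boltzmann) populations from exponentially
# distributed true energies, DFT-like Gaussian errors on the reported
# energies, sub-linewidth frequency errors between "true" and "computed"
# stick frequencies, and Gaussian baseline noise on the experiment.

#' Synthetic-ensemble configuration
#'
#' @param n_conformers number of conformers (>= 1).
#' @param n_modes normal modes per conformer.
#' @param freq_range wavenumber range of the modes (cm^-1).
#' @param dipole_meanlog,dipole_sdlog log-normal law of dipole strengths.
#' @param rot_sigma_scale sd of rotational strengths as a fraction of the
#'   mean dipole strength.
#' @param sign_opposition fraction of modes shared across conformers with
#'   randomly flipped VCD sign — the "features with opposing signs" regime
#'   that makes conformer weighting consequential.
#' @param energy_mean mean of the exponential law of true relative energies
#'   (kcal/mol).
#' @param energy_error_sd sd of the Gaussian error between true and reported
#'   energies (kcal/mol); 1-2.5 mimics DFT energy uncertainty.
#' @param baseline_noise sd of the experimental baseline noise as a fraction
#'   of the maximum absolute intensity.
#' @param freq_perturb_sd sd of the per-mode error between true and reported
#'   stick frequencies (cm^-1); sub-linewidth by default.
#' @param rot_error_sd sd of the per-mode error between true and reported
#'   rotational strengths, as a multiple of the rotational-strength scale;
#'   0 by default.  Nonzero values emulate the intensity (and sign) errors
#'   of computed VCD spectra, the error source that makes overfitting
#'   possible: local misfit that extra conformers can patch without the
#'   patch generalizing.
#' @param true_energies optional explicit vector of true relative energies
#'   overriding the exponential draw (length `n_conformers`).
#' @param seed RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_conformers, n_modes = 30, freq_range = c(950, 1650),
                         dipole_meanlog = 0, dipole_sdlog = 0.8,
                         rot_sigma_scale = 0.05, sign_opposition = 0.3,
                         energy_mean = 1, energy_error_sd = 1,
                         baseline_noise = 0.02, freq_perturb_sd = 3,
                         rot_error_sd = 0, true_energies = NULL, seed = 1) {
  if (!is_scalar_number(n_conformers) || n_conformers < 1) {
    stopf("n_conformers must be >= 1")
  }
  for (s in c(dipole_sdlog, rot_sigma_scale, energy_mean, energy_error_sd,
              baseline_noise, freq_perturb_sd, rot_error_sd)) {
    if (s < 0) stopf("all sigmas must be >= 0")
  }
  if (sign_opposition < 0 || sign_opposition > 1) {
    stopf("sign_opposition must lie in [0, 1]")
  }
  if (!is.null(true_energies) && length(true_energies) != n_conformers) {
    stopf("true_energies must have length n_conformers")
  }
  structure(list(n_conformers = as.integer(n_conformers),
                 n_modes = as.integer(n_modes), freq_range = freq_range,
                 dipole_meanlog = dipole_meanlog, dipole_sdlog = dipole_sdlog,
                 rot_sigma_scale = rot_sigma_scale,
                 sign_opposition = sign_opposition, energy_mean = energy_mean,
                 energy_error_sd = energy_error_sd,
                 baseline_noise = baseline_noise,
                 freq_perturb_sd = freq_perturb_sd,
                 rot_error_sd = rot_error_sd,
                 true_energies = true_energies, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic conformer ensemble with known ground truth
#'
#' Returns both the "reported" ensemble a user would feed to the fit
#' (energies corrupted by Gaussian error, stick frequencies perturbed) and
#' the hidden truth (exact energies and frequencies, true Boltzmann
#' weights) from which pseudo-experiments are built.
#'
#' @param cfg a [synth_config()].
#' @param thermo a [thermo_config()] for the true weights.
#' @return an object of class `synth_ensemble`: list with `ensemble` (the
#'   reported one), `truth` (`true_energies`, `true_weights`,
#'   `reported_energies`, `true_ensemble`) and the configuration.
#' @export
generate_ensemble <- function(cfg, thermo = thermo_config()) {
  n <- cfg$n_conformers
  m <- cfg$n_modes
  dip_scale <- exp(cfg$dipole_meanlog + cfg$dipole_sdlog^2 / 2)
  rot_sd <- cfg$rot_sigma_scale * dip_scale
  with_seed(cfg$seed, {
    n_shared <- round(cfg$sign_opposition * m)
    shared_freq <- sort(stats::runif(n_shared, cfg$freq_range[1], cfg$freq_range[2]))
    shared_dip <- stats::rlnorm(n_shared, cfg$dipole_meanlog, cfg$dipole_sdlog)
    shared_rot_mag <- abs(stats::rnorm(n_shared, 0, rot_sd))
    true_sticks <- vector("list", n)
    pert_sticks <- vector("list", n)
    for (i in seq_len(n)) {
      own <- m - n_shared
      freq <- c(shared_freq, stats::runif(own, cfg$freq_range[1], cfg$freq_range[2]))
      dip <- c(shared_dip, stats::rlnorm(own, cfg$dipole_meanlog, cfg$dipole_sdlog))
      rot <- c(shared_rot_mag * sample(c(-1, 1), n_shared, replace = TRUE),
               stats::rnorm(own, 0, rot_sd))
      true_sticks[[i]] <- stick_spectrum(freq, dip, rot)
      pfreq <- pmax(1, freq + stats::rnorm(m, 0, cfg$freq_perturb_sd))
      prot <- rot + stats::rnorm(m, 0, cfg$rot_error_sd * rot_sd)
      pert_sticks[[i]] <- stick_spectrum(pfreq, dip, prot)
    }
    true_e <- if (is.null(cfg$true_energies)) {
      stats::rexp(n, rate = 1 / max(cfg$energy_mean, 1e-12))
    } else {
      as.numeric(cfg$true_energies)
    }
    true_e <- true_e - min(true_e)
    reported_e <- true_e + stats::rnorm(n, 0, cfg$energy_error_sd)
    ids <- sprintf("c%03d", seq_len(n))
    reported <- vcd_ensemble(lapply(seq_len(n), function(i) {
      conformer_record(ids[i], reported_e[i], pert_sticks[[i]])
    }))
    truth_ens <- vcd_ensemble(lapply(seq_len(n), function(i) {
      conformer_record(ids[i], true_e[i], true_sticks[[i]])
    }))
    structure(list(ensemble = reported,
                   truth = list(true_energies = true_e,
                                true_weights = boltzmann_weights(true_e, thermo),
                                reported_energies = reported_e,
                                true_ensemble = truth_ens),
                   cfg = cfg, seed = cfg$seed),
              class = "synth_ensemble")
  })
}

#' Build the pseudo-experimental VA and VCD spectra of a synthetic ensemble
#'
#' The experiment is composed from the TRUE stick frequencies and TRUE
#' Boltzmann weights, plus Gaussian baseline noise — while the ensemble a
#' fit receives carries the perturbed frequencies and corrupted energies,
#' so recovering the weights is non-trivial in exactly the way real data
#' make it.
#'
#' @param syn a `synth_ensemble` from [generate_ensemble()].
#' @param cfg a [broadening_config()].
#' @param noise_sd optional override of the baseline-noise fraction.
#' @return list with elements `va` and `vcd` ([continuous_spectrum()]s).
#' @export
generate_experiment <- function(syn, cfg = broadening_config(),
                                noise_sd = NULL) {
  if (!inherits(syn, "synth_ensemble")) stopf("syn must come from generate_ensemble")
  frac <- if (is.null(noise_sd)) syn$cfg$baseline_noise else noise_sd
  w <- syn$truth$true_weights
  va <- composite_spectrum(syn$truth$true_ensemble, w, "VA", cfg)
  vcd <- composite_spectrum(syn$truth$true_ensemble, w, "VCD", cfg)
  # decouple the noise stream from the ensemble-generation stream
  with_seed(syn$seed %% 1000000L + 500000L, {
    add_noise <- function(sp) {
      s <- frac * max(abs(sp$values))
      continuous_spectrum(sp$grid, sp$values + stats::rnorm(length(sp$values), 0, s),
                          mode = sp$mode)
    }
    list(va = add_noise(va), vcd = add_noise(vcd))
  })
}

#' The canonical overfitting fixture: few informative, many redundant
#' conformers
#'
#' Sixty conformers of which only the five lowest-energy ones carry true
#' weight above 0.01; the remaining 55 sit at true energies >= 3.2 kcal/mol
#' (negligible true population).  Reported energies carry 1 kcal/mol of
#' Gaussian error, the experiment has a poor baseline (10% noise), and the
#' reported rotational strengths carry mode-local errors (sd half the
#' strength scale).  The local intensity misfit gives the redundant
#' conformers something to patch on any particular stretch of the spectrum
#' -- the regime in which fitted weights of high-energy conformers are
#' statistically meaningless.
#'
#' @param seed RNG seed.
#' @param n_redundant number of redundant conformers.
#' @return a `synth_ensemble`.
#' @export
generate_overfit_ensemble <- function(seed = 1, n_redundant = 55) {
  true_e <- c(0, 0.3, 0.6, 0.9, 1.2,
              3.2 + 2.5 * (seq_len(n_redundant) - 1) / n_redundant)
  generate_ensemble(synth_config(n_conformers = 5L + n_redundant,
                                 true_energies = true_e,
                                 energy_error_sd = 1, baseline_noise = 0.1,
                                 rot_error_sd = 0.5, seed = seed))
}

#' The canonical enantiomer-discrimination fixture: opposing-band conformers
#'
#' Five thermally populated conformers (energy ladder 0-1.2 kcal/mol) plus a
#' pool of higher-energy conformers among which, for each populated
#' conformer, there are partial mirrors: copies whose rotational strengths
#' are sign-flipped on the subset of modes carrying about a fraction `q` of
#' the VCD power (largest modes first), with identical VA intensities.
#' Such conformers carry "features of both enantiomers": fitting the
#' mirrored experiment can reach an overlap of roughly `2q - 1` by
#' populating the partial mirrors, well above the 0.4 assignment threshold,
#' while the fit to the correct enantiomer stays far better -- the
#' situation in which only the overlap difference, not the absolute mirror
#' overlap, discriminates.
#'
#' @param seed RNG seed.
#' @param q fraction of VCD power sign-flipped in the partial mirrors.
#' @return a `synth_ensemble`.
#' @export
generate_enantiomer_ensemble <- function(seed = 1, q = 0.7) {
  n_pop <- 5L; n_mirror_each <- 3L; n_filler <- 40L
  n <- n_pop + n_pop * n_mirror_each + n_filler
  with_seed(seed, {
    pop_e <- c(0, 0.3, 0.6, 0.9, 1.2)
    mirror_e <- stats::runif(n_pop * n_mirror_each, 1.5, 2.5)
    filler_e <- stats::runif(n_filler, 2, 4)
    true_e <- c(pop_e, mirror_e, filler_e)
  })
  cfg <- synth_config(n_conformers = n, n_modes = 60, freq_perturb_sd = 1.5,
                      true_energies = true_e, seed = seed)
  syn <- generate_ensemble(cfg)
  # rebuild the mirror-pool conformers as partial mirrors of the populated
  # ones, in both the true and the reported ensembles
  flip_set <- function(rot) {
    o <- order(abs(rot), decreasing = TRUE)
    pw <- cumsum(rot[o]^2) / sum(rot^2)
    o[seq_len(which(pw >= q)[1])]
  }
  for (j in seq_len(n_pop * n_mirror_each)) {
    parent <- ((j - 1L) %% n_pop) + 1L
    tgt <- n_pop + j
    src <- syn$truth$true_ensemble$conformers[[parent]]$sticks
    fl <- flip_set(src$rotational_strengths)
    rot <- src$rotational_strengths; rot[fl] <- -rot[fl]
    syn$truth$true_ensemble$conformers[[tgt]]$sticks <-
      stick_spectrum(src$frequencies, src$dipole_strengths, rot)
    # reported copy: same flip rule applied to the perturbed parent sticks
    srcp <- syn$ensemble$conformers[[parent]]$sticks
    flp <- flip_set(srcp$rotational_strengths)
    rotp <- srcp$rotational_strengths; rotp[flp] <- -rotp[flp]
    syn$ensemble$conformers[[tgt]]$sticks <-
      stick_spectrum(srcp$frequencies, srcp$dipole_strengths, rotp)
  }
  # stick data changed: reset the broadened-spectrum caches
  syn$ensemble <- vcd_ensemble(syn$ensemble$conformers)
  syn$truth$true_ensemble <- vcd_ensemble(syn$truth$true_ensemble$conformers)
  syn
}

#' Write the canonical test-fixture suite to disk
#'
#' Materializes, in the manifest/stick/two-column formats the readers
#' consume, the fixtures the validation machinery is exercised on: a
#' 2-conformer oracle set, the 5-informative/55-redundant overfitting set,
#' a strongly sign-opposed enantiomer set, and energy-corruption sets at
#' sd 0, 1 and 2.5 kcal/mol.  Each fixture directory holds the ensemble,
#' the pseudo-experimental spectra and a ground-truth sidecar; a checksum
#' file makes regeneration verifiable.
#'
#' @param out_dir output directory.
#' @param seed base RNG seed.
#' @param cfg a [broadening_config()].
#' @return named vector of fixture directories, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, cfg = broadening_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    oracle2 = synth_config(n_conformers = 2, seed = seed),
    overfit60 = NULL,  # built by generate_overfit_ensemble
    enantiomer = NULL,  # built by generate_enantiomer_ensemble
    sigma0 = synth_config(n_conformers = 40, energy_error_sd = 0,
                          freq_perturb_sd = 0, baseline_noise = 0,
                          seed = seed + 3L),
    sigma1 = synth_config(n_conformers = 40, energy_error_sd = 1, seed = seed + 4L),
    sigma2.5 = synth_config(n_conformers = 40, energy_error_sd = 2.5,
                            seed = seed + 5L))
  dirs <- character(0)
  for (nm in names(specs)) {
    syn <- switch(nm,
                  overfit60 = generate_overfit_ensemble(seed + 1L),
                  enantiomer = generate_enantiomer_ensemble(seed + 2L),
                  generate_ensemble(specs[[nm]]))
    exper <- generate_experiment(syn, cfg)
    d <- file.path(out_dir, nm)
    write_ensemble(syn$ensemble, d)
    write_spectrum(exper$va, file.path(d, "exp_va.dat"))
    write_spectrum(exper$vcd, file.path(d, "exp_vcd.dat"))
    utils::write.csv(data.frame(id = syn$ensemble$ids,
                                true_energy = syn$truth$true_energies,
                                true_weight = syn$truth$true_weights,
                                reported_energy = syn$truth$reported_energies),
                     file.path(d, "ground_truth.csv"), row.names = FALSE,
                     quote = FALSE)
    dirs[nm] <- d
  }
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "CHECKSUMS"]
  sums <- tools::md5sum(files)
  writeLines(sprintf("%s  %s", sums, sub(paste0("^", out_dir, "/?"), "",
                                         names(sums))),
             file.path(out_dir, "CHECKSUMS"))
  invisible(dirs)
}
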