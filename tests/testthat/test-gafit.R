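test_that("a single-conformer fit has no free parameters", {
  ens <- vcd_ensemble(list(conformer_record("only", 0,
                                            stick_spectrum(c(1000, 1400),
                                                           c(1, 1),
                                                           c(0.3, -0.5)))))
  exp_vcd <- broaden(ens$conformers[[1]]$sticks, "VCD")
  fit <- fit_energies(ens, exp_vcd, demax = 1, ga = quick_ga())
  expect_equal(fit$weights, 1)
  expect_equal(fit$sim_vcd, 1)
})

test_that("two-conformer fits match the exhaustive 1-D oracle", {
  for (r in 1:5) {
    syn <- generate_ensemble(synth_config(n_conformers = 2, seed = 20 + r))
    ex <- generate_experiment(syn)
    fit <- fit_energies(syn$ensemble, ex$vcd, demax = 2,
                        ga = quick_ga(seed = r, pop = 48, gens = 120))
    best <- oracle_two_conformer(syn$ensemble, ex$vcd, demax = 2)
    expect_gte(fit$sim_vcd, best - 0.005)
  }
})

test_that("true weights are recovered on a clean two-conformer problem", {
  syn <- generate_ensemble(synth_config(n_conformers = 2, seed = 31,
                                        freq_perturb_sd = 0, baseline_noise = 0,
                                        energy_error_sd = 0,
                                        true_energies = c(0, 0.5)))
  ex <- generate_experiment(syn)
  fit <- fit_energies(syn$ensemble, ex$vcd, demax = 2,
                      ga = quick_ga(seed = 2, pop = 48, gens = 120))
  expect_equal(unname(fit$weights), syn$truth$true_weights, tolerance = 0.02)
  expect_gte(fit$sim_vcd, 0.999)
})

test_that("the bound demax -> 0 reproduces plain Boltzmann weighting", {
  syn <- generate_ensemble(synth_config(n_conformers = 4, seed = 2))
  ex <- generate_experiment(syn)
  fit <- fit_energies(syn$ensemble, ex$vcd, demax = 1e-9,
                      ga = quick_ga(pop = 16, gens = 15))
  bw <- boltzmann_weights(syn$ensemble$energies)
  expect_equal(unname(fit$weights), bw, tolerance = 1e-6)
  expect_equal(fit$sim_vcd,
               sim_overlap(composite_spectrum(syn$ensemble, bw, "VCD"), ex$vcd),
               tolerance = 1e-9)
})

test_that("the fitted overlap never falls below the Boltzmann overlap", {
  for (r in 1:3) {
    syn <- generate_ensemble(synth_config(n_conformers = 6, seed = 40 + r))
    ex <- generate_experiment(syn)
    bw_ov <- sim_overlap(composite_spectrum(syn$ensemble,
                                            boltzmann_weights(syn$ensemble$energies),
                                            "VCD"), ex$vcd)
    fit <- fit_energies(syn$ensemble, ex$vcd, demax = 1,
                        ga = quick_ga(seed = r, pop = 24, gens = 40))
    expect_gte(fit$sim_vcd, bw_ov - 1e-12)
    expect_false(is.unsorted(fit$history))        # elitism: monotone history
    expect_true(all(abs(fit$deltas) <= 1 + 1e-9)) # bound respected
  }
})

test_that("the same seed gives a bit-identical fit", {
  syn <- generate_ensemble(synth_config(n_conformers = 5, seed = 3))
  ex <- generate_experiment(syn)
  f1 <- fit_energies(syn$ensemble, ex$vcd, demax = 1, ga = quick_ga(seed = 7))
  f2 <- fit_energies(syn$ensemble, ex$vcd, demax = 1, ga = quick_ga(seed = 7))
  expect_identical(f1$deltas, f2$deltas)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$sim_vcd, f2$sim_vcd)
})

test_that("free fits ignore the starting energies", {
  ga <- quick_ga(seed = 3, pop = 96, gens = 250)
  syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 5))
  ex <- generate_experiment(syn)
  f1 <- fit_free(syn$ensemble, ex$vcd, ga = ga)
  shifted <- vcd_ensemble(lapply(seq_len(3), function(i) {
    cf <- syn$ensemble$conformers[[i]]
    conformer_record(cf$id, cf$energy + c(5, -2, 1)[i], cf$sticks)
  }))
  f2 <- fit_free(shifted, ex$vcd, ga = ga)
  expect_equal(unname(f1$weights), unname(f2$weights), tolerance = 0.01)
  # an experiment equal to one conformer's spectrum pins the weight on it
  target <- composite_spectrum(syn$ensemble, c(0, 0, 1), "VCD")
  f3 <- fit_free(syn$ensemble, target, ga = ga)
  expect_gte(f3$weights[3], 0.98)
})

test_that("identical conformer spectra are a flat direction, not an error", {
  st <- stick_spectrum(c(1000, 1300), c(1, 2), c(0.5, -0.3))
  ens <- vcd_ensemble(list(conformer_record("a", 0, st),
                           conformer_record("b", 0.3, st)))
  exp_vcd <- broaden(st, "VCD")
  fit <- fit_energies(ens, exp_vcd, demax = 2, ga = quick_ga(pop = 16, gens = 15))
  expect_equal(fit$sim_vcd, 1, tolerance = 1e-9)
  sm <- summary(fit)
  expect_equal(nrow(sm$flat), 1)  # the collinear pair is reported
})

test_that("window scans agree across methods in forced-agreement limits", {
  syn <- generate_ensemble(synth_config(n_conformers = 5, seed = 6,
                                        true_energies = c(0, 1, 1, 2, 3),
                                        energy_error_sd = 0))
  ex <- generate_experiment(syn)
  wg <- c(0.5, 1.5, 3.5)
  tmean <- overlap_vs_window(syn$ensemble, ex$vcd, wg, "mean")
  tbw <- overlap_vs_window(syn$ensemble, ex$vcd, wg, "bw")
  tfit <- overlap_vs_window(syn$ensemble, ex$vcd, wg, "fitted", demax = 1,
                            ga = quick_ga(pop = 24, gens = 40))
  # single conformer below the 2nd-lowest energy: all methods coincide
  expect_equal(tmean$overlap[1], tbw$overlap[1])
  expect_equal(tmean$overlap[1], tfit$overlap[1])
  # the fitted curve dominates the Boltzmann curve everywhere
  expect_true(all(tfit$overlap >= tbw$overlap - 1e-12))
  # equal retained energies make mean and bw identical (conformers 2 and 3)
  sub <- vcd_ensemble(syn$ensemble$conformers[2:3])
  expect_equal(sim_overlap(composite_spectrum(sub, arithmetic_weights(2), "VCD"),
                           ex$vcd),
               sim_overlap(composite_spectrum(sub, boltzmann_weights(sub$energies),
                                              "VCD"), ex$vcd))
  expect_error(overlap_vs_window(syn$ensemble, ex$vcd, c(2, 1), "bw"),
               "ascending")
})

test_that("vcdfit methods expose the fit coherently", {
  syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 13))
  ex <- generate_experiment(syn)
  fit <- vcdfit(syn$ensemble, ex$vcd, ex$va, demax = 1, ga = quick_ga())
  expect_s3_class(fit, "vcdfit")
  expect_named(coef(fit), syn$ensemble$ids)
  expect_equal(sum(weights(fit)), 1, tolerance = 1e-12)
  expect_equal(fitted(fit, "VCD")$values,
               composite_spectrum(syn$ensemble, fit$weights, "VCD")$values)
  r <- residuals(fit, "VCD")
  expect_equal(unname(r[!is.na(r)]),
               (ex$vcd$values - fitted(fit, "VCD")$values)[ex$vcd$measured])
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$values, sims[[2]]$values))
  expect_output(print(fit), "SimVCD")
  expect_output(print(summary(fit)), "Leading conformer")
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); plot(ex$vcd); grDevices::dev.off()
  expect_true(file.exists(pf))
})
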