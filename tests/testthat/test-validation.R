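test_that("cross-validation folds partition the masked grid exactly", {
  syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 2))
  ex <- generate_experiment(syn)
  mask <- exclude_region(900, 1701, c(1200, 1400))
  keep <- ex$vcd$measured & vcdfit:::mask_keep(mask, ex$vcd$grid)
  blocks <- vcdfit:::spectral_blocks(ex$vcd$grid, keep, 16)
  idx <- sort(unlist(blocks))
  expect_equal(idx, which(keep))                  # exact partition, no overlap
  expect_equal(anyDuplicated(unlist(blocks)), 0L)
  # block widths are near 2*FWHM except for run remainders
  expect_true(all(lengths(blocks) >= 8))
})

test_that("a generating model inside the hypothesis set cross-validates cleanly", {
  syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 2,
                                        freq_perturb_sd = 0, baseline_noise = 0,
                                        energy_error_sd = 0))
  ex <- generate_experiment(syn)
  cv <- kfold_cv(syn$ensemble, ex$vcd, k = 5, demax = 1,
                 ga = quick_ga(pop = 24, gens = 40), seed = 1)
  expect_gte(cv$mean_test, 0.99)
  expect_error(kfold_cv(syn$ensemble, ex$vcd, k = 1), ">= 2")
})

test_that("pooled and per-fold test summaries are both available", {
  syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 4))
  ex <- generate_experiment(syn)
  cv1 <- kfold_cv(syn$ensemble, ex$vcd, k = 3, demax = 1,
                  ga = quick_ga(pop = 16, gens = 20), seed = 2)
  cv2 <- kfold_cv(syn$ensemble, ex$vcd, k = 3, demax = 1,
                  ga = quick_ga(pop = 16, gens = 20), seed = 2,
                  combine = "pooled")
  expect_equal(cv1$fold_test, cv2$fold_test)  # same folds, same fits
  expect_true(is.finite(cv2$mean_test))
  expect_output(print(cv1), "cross-validation")
})

test_that("mirroring the ensemble swaps the enantiomer-test overlaps exactly", {
  syn <- generate_ensemble(synth_config(n_conformers = 4, seed = 6))
  ex <- generate_experiment(syn)
  ga <- quick_ga(pop = 24, gens = 30)
  et1 <- enantiomer_test(syn$ensemble, ex$vcd, demax = 1, ga = ga)
  et2 <- enantiomer_test(mirror_ensemble(syn$ensemble), ex$vcd, demax = 1,
                         ga = ga)
  expect_equal(et1$sim_correct, et2$sim_mirror)
  expect_equal(et1$sim_mirror, et2$sim_correct)
  expect_equal(et1$delta, -et2$delta)
})

test_that("self and mirrored experiments give opposite verdicts", {
  syn <- generate_ensemble(synth_config(n_conformers = 4, seed = 6,
                                        baseline_noise = 0,
                                        freq_perturb_sd = 0,
                                        energy_error_sd = 0))
  ex <- generate_experiment(syn)
  ga <- quick_ga(pop = 24, gens = 40)
  et <- enantiomer_test(syn$ensemble, ex$vcd, demax = 1, ga = ga)
  expect_equal(et$sim_correct, 1, tolerance = 1e-6)
  expect_equal(et$verdict, "assigned")
  flipped <- continuous_spectrum(ex$vcd$grid, -ex$vcd$values, "VCD")
  etm <- enantiomer_test(syn$ensemble, flipped, demax = 1, ga = ga)
  expect_lte(etm$delta, 0)
  expect_equal(etm$verdict, "inconclusive")
})

test_that("the energy-uncertainty estimate is invariant to uniform shifts", {
  syn <- generate_ensemble(synth_config(n_conformers = 20, seed = 9))
  ex <- generate_experiment(syn)
  eu1 <- estimate_energy_uncertainty(syn$ensemble, ex$vcd)
  shifted <- vcd_ensemble(lapply(syn$ensemble$conformers, function(cf) {
    conformer_record(cf$id, cf$energy + 4.2, cf$sticks)
  }))
  eu2 <- estimate_energy_uncertainty(shifted, ex$vcd)
  expect_equal(eu1$estimate, eu2$estimate)
  expect_equal(eu1$table$bw_overlap, eu2$table$bw_overlap)
  expect_error(estimate_energy_uncertainty(syn$ensemble, ex$vcd, numeric(0)),
               "empty")
})

test_that("removing an inactive conformer costs nothing, an active one does", {
  ga <- quick_ga(pop = 48, gens = 80)
  syn <- generate_ensemble(synth_config(n_conformers = 4, seed = 21,
                                        true_energies = c(0, 0.5, 1.4, 9),
                                        energy_error_sd = 0,
                                        baseline_noise = 0.01))
  ex <- generate_experiment(syn)
  # the 9 kcal/mol conformer has essentially zero weight everywhere
  inert <- conformer_necessity(syn$ensemble, ex$vcd, "c004", demax = 1,
                               ga = ga)
  expect_lte(abs(inert$difference), 0.001)
  # a conformer holding ~24% of the truth is missed when removed
  active <- conformer_necessity(syn$ensemble, ex$vcd, "c002", demax = 1,
                                ga = ga)
  expect_gt(active$difference, 0.01)
  expect_error(conformer_necessity(syn$ensemble, ex$vcd, "zzz", 1), "unknown")
  one <- vcd_ensemble(syn$ensemble$conformers[1])
  expect_error(conformer_necessity(one, ex$vcd, "c001", 1), "singleton")
})
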