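test_that("stick spectrum and ensemble invariants are enforced", {
  expect_error(stick_spectrum(c(100, 200), c(1), c(1, 2)), "equal length")
  expect_error(stick_spectrum(c(-5, 200), c(1, 1), c(1, 2)), "positive")
  expect_error(stick_spectrum(c(100, 200), c(-1, 1), c(1, 2)), "non-negative")
  cfs <- list(conformer_record("x", 2, stick_spectrum(1000, 1, 0.1)),
              conformer_record("y", 1, stick_spectrum(1100, 1, 0.1)),
              conformer_record("z", 3, stick_spectrum(1200, 1, 0.1)))
  ens <- vcd_ensemble(cfs)
  expect_equal(ens$energies, c(1, 0, 2))  # min-shifted
  expect_error(vcd_ensemble(list(cfs[[1]], cfs[[1]])), "duplicate")
  one <- vcd_ensemble(cfs[1])
  expect_equal(one$energies, 0)
})

test_that("Lorentzian broadening has unit-area kernels and is linear", {
  cfg <- broadening_config(fwhm = 8, grid_lo = 800, grid_hi = 1600,
                           grid_step = 1)
  empty <- broaden(stick_spectrum(numeric(0), numeric(0), numeric(0)),
                   "VCD", cfg)
  expect_true(all(empty$values == 0))
  one <- broaden(stick_spectrum(1200, 1, 1), "VA", cfg)
  # peak height of a unit-strength mode is 2/(pi*Gamma)
  expect_equal(one$values[one$grid == 1200], 2 / (pi * 8), tolerance = 1e-6)
  # trapezoidal integral over +-400 cm^-1 recovers the strength within 1%
  integral <- sum(vcdfit:::trap_weights(one$grid) * one$values)
  expect_equal(integral, 1, tolerance = 0.01)
  sc <- broaden(stick_spectrum(1200, 3.5, 3.5), "VA", cfg)
  expect_equal(sc$values, 3.5 * one$values)
  # additivity over modes
  two <- broaden(stick_spectrum(c(1100, 1300), c(1, 2), c(0, 0)), "VA", cfg)
  sep <- broaden(stick_spectrum(1100, 1, 0), "VA", cfg)$values +
    broaden(stick_spectrum(1300, 2, 0), "VA", cfg)$values
  expect_equal(two$values, sep)
})

test_that("broadened integral matches total strength for a multi-mode ensemble", {
  syn <- generate_ensemble(synth_config(n_conformers = 1, seed = 42,
                                        freq_range = c(1150, 1450)))
  sticks <- syn$ensemble$conformers[[1]]$sticks
  cfg <- broadening_config(grid_lo = 600, grid_hi = 2000, grid_step = 1)
  sp <- broaden(sticks, "VA", cfg)
  integral <- sum(vcdfit:::trap_weights(sp$grid) * sp$values)
  expect_equal(integral, sum(sticks$dipole_strengths), tolerance = 0.01)
})

test_that("frequency scaling multiplies frequencies only, within bounds", {
  st <- stick_spectrum(c(1000, 1500), c(1, 2), c(0.1, -0.2))
  expect_equal(scale_frequencies(st, 1), st)
  sc <- scale_frequencies(st, 0.98)
  expect_equal(sc$frequencies, c(980, 1470))
  expect_equal(sc$dipole_strengths, st$dipole_strengths)
  expect_error(scale_frequencies(st, 1.2), "0.9")
})

test_that("region masks include, exclude, and reject empty coverage", {
  cfg <- broadening_config()
  sp <- continuous_spectrum(cfg$grid, sin(cfg$grid / 50), "VCD")
  full <- apply_mask(sp, region_mask(c(900, 1701)))
  expect_equal(full$values, sp$values)
  m <- exclude_region(900, 1701, c(1200, 1400))
  cut <- apply_mask(sp, m)
  expect_false(any(cut$grid >= 1200 & cut$grid < 1400))
  expect_true(all(sp$grid[sp$grid < 1200 | sp$grid >= 1400] %in% cut$grid))
  expect_error(apply_mask(sp, region_mask(c(5000, 6000))), "no grid point")
  expect_error(region_mask(rbind(c(1000, 1300), c(1200, 1400))), "overlap")
  # masking a region where two spectra agree keeps identical spectra at +1
  expect_equal(sim_overlap(sp, sp, similarity_config(mask = m)), 1)
})

test_that("two-column spectra round-trip through disk, any row order", {
  cfg <- broadening_config(grid_lo = 1000, grid_hi = 1100, grid_step = 1)
  f <- tempfile(fileext = ".dat")
  pts <- data.frame(x = c(1000, 1025, 1050, 1075, 1100), y = c(1, -2, 3, 0, 5))
  writeLines(sprintf("%g %g", pts$x, pts$y), f)
  sp <- read_experimental_spectrum(f, "VCD", cfg)
  expect_equal(sp$values[match(pts$x, sp$grid)], pts$y)
  # descending order reads identically
  writeLines(sprintf("%g, %g", rev(pts$x), rev(pts$y)), f)
  sp2 <- read_experimental_spectrum(f, "VCD", cfg)
  expect_equal(sp2$values, sp$values)
  # write/read round trip is lossless
  g <- tempfile(fileext = ".dat")
  write_spectrum(sp, g)
  sp3 <- read_experimental_spectrum(g, "VCD", cfg)
  expect_equal(sp3$values, sp$values)
  expect_error(read_experimental_spectrum(tempfile(), "VCD", cfg), "not found")
  writeLines("1000 1 7", f)
  expect_error(read_experimental_spectrum(f, "VCD", cfg), "two columns")
  writeLines(c("1000 1", "1000 2"), f)
  expect_error(read_experimental_spectrum(f, "VCD", cfg), "duplicate")
})

test_that("points outside the measured range are flagged and excluded", {
  cfg <- broadening_config(grid_lo = 900, grid_hi = 1700, grid_step = 1)
  f <- tempfile(fileext = ".dat")
  writeLines(sprintf("%g %g", seq(1000, 1400, 10), rnorm(41)), f)
  sp <- read_experimental_spectrum(f, "VCD", cfg)
  expect_true(all(sp$values[!sp$measured] == 0))
  expect_equal(range(sp$grid[sp$measured]), c(1000, 1400))
})

test_that("JCAMP-DX XYDATA and XYPOINTS dialects parse", {
  cfg <- broadening_config(grid_lo = 1000, grid_hi = 1004, grid_step = 1)
  f <- tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=synthetic test block", "##JCAMP-DX=4.24",
               "##XFACTOR=1", "##YFACTOR=0.5", "##FIRSTX=1000", "##LASTX=1004",
               "##NPOINTS=5", "##DELTAX=1", "##XYDATA=(X++(Y..Y))",
               "1000 2 4 6", "1003 8 10", "##END="), f)
  sp <- read_experimental_spectrum(f, "VA", cfg)
  expect_equal(sp$values, c(1, 2, 3, 4, 5))
  writeLines(c("##TITLE=synthetic test block", "##XYPOINTS=(XY..XY)",
               "1000,1; 1002,3", "1004,5", "##END="), f)
  sp2 <- read_experimental_spectrum(f, "VA", cfg)
  expect_equal(sp2$values, c(1, 2, 3, 4, 5))
})

test_that("ensemble manifests round-trip and readers enforce the contract", {
  syn <- generate_ensemble(synth_config(n_conformers = 3, n_modes = 5, seed = 9))
  d <- tempfile()
  manifest <- write_ensemble(syn$ensemble, d)
  back <- read_conformer_ensemble(manifest)
  expect_equal(back$ids, syn$ensemble$ids)
  expect_equal(back$energies, syn$ensemble$energies, tolerance = 1e-10)
  expect_equal(back$conformers[[2]]$sticks$frequencies,
               syn$ensemble$conformers[[2]]$sticks$frequencies,
               tolerance = 1e-10)
  # duplicate id
  man <- read.csv(manifest)
  man$id <- c("c1", "c1", "c2")
  write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  expect_error(read_conformer_ensemble(manifest), "duplicate")
  # missing stick file
  man$id <- c("c1", "c2", "c3"); man$sticks_path[2] <- "nope.dat"
  write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  expect_error(read_conformer_ensemble(manifest), "missing")
})

test_that("the VA scaling factor is recovered by grid search with ties to 1", {
  syn <- generate_ensemble(synth_config(n_conformers = 3, seed = 8,
                                        freq_perturb_sd = 0, baseline_noise = 0))
  ens <- syn$truth$true_ensemble
  w <- syn$truth$true_weights
  self_va <- composite_spectrum(ens, w, "VA")
  expect_equal(optimize_scaling(ens, w, self_va, bounds = c(0.97, 1.03)), 1)
  shifted <- composite_spectrum(scale_ensemble(ens, 0.98), w, "VA")
  expect_equal(optimize_scaling(ens, w, shifted, bounds = c(0.95, 1.05)), 0.98,
               tolerance = 1e-9)
  # a flat overlap profile (single Lorentzian vs itself anywhere) ties to 1
  expect_error(optimize_scaling(ens, w, self_va, bounds = c(0.8, 1.05)),
               "within")
})
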