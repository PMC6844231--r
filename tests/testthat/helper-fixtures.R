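# Shared test helpers: tiny deterministic fixtures and a fast GA config.

quick_ga <- function(seed = 1, pop = 32, gens = 60) {
  ga_config(population_size = pop, generations = gens, seed = seed)
}

# a tiny hand-built ensemble with well-separated, distinguishable spectra
toy_ensemble <- function() {
  vcd_ensemble(list(
    conformer_record("a", 0.0, stick_spectrum(c(1000, 1300), c(1, 2), c(0.5, -0.3))),
    conformer_record("b", 0.5, stick_spectrum(c(1100, 1500), c(1.5, 1), c(-0.4, 0.6))),
    conformer_record("c", 1.2, stick_spectrum(c(1200, 1600), c(2, 0.5), c(0.2, 0.7)))
  ))
}

# independent oracle for 2-conformer energy-modulation fits: exhaustive scan
# over the only identifiable parameter, the modulation difference d2 - d1,
# evaluating the cosine overlap directly from the broadened spectra
oracle_two_conformer <- function(ens, exp_vcd, demax, cfg = broadening_config(),
                                 thermo = thermo_config(), step = 0.001) {
  kT <- thermo$k_B * thermo$temperature
  e <- ens$energies
  M <- vapply(ens$conformers, function(cf) broaden(cf$sticks, "VCD", cfg)$values,
              numeric(length(cfg$grid)))
  keep <- exp_vcd$measured
  wq <- vcdfit:::trap_weights(exp_vcd$grid, keep)
  g <- exp_vcd$values[keep]
  M <- M[keep, , drop = FALSE]
  d <- seq(-2 * demax, 2 * demax, by = step)
  w2 <- 1 / (1 + exp((e[2] - e[1] + d) / kT))
  W <- rbind(1 - w2, w2)
  C <- M %*% W
  num <- as.vector(crossprod(C, wq * g))
  ff <- colSums(C * C * wq)
  gg <- sum(wq * g * g)
  max(num / sqrt(ff * gg))
}
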