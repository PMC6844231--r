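Package: vcdfit
Title: Conformer Population Fitting for Vibrational Circular Dichroism Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits an experimental vibrational circular dichroism (VCD) and/or
    vibrational absorption (VA) spectrum as a Boltzmann-weighted sum of computed
    conformer spectra, allowing the conformer energies to deviate from their
    computed values by at most a bound dE_max that encodes the uncertainty of
    quantum-chemical energies. The optimization is performed with a genetic
    algorithm maximizing a normalized spectral overlap (SimVCD). Confidence in
    the resulting absolute-configuration assignment is quantified through
    k-fold cross-validation over spectral blocks, a two-enantiomer
    discrimination test, an empirical estimator of the energy uncertainty, and
    conformer-necessity refits. Includes Lorentzian line broadening, frequency
    scaling, region masking, readers for simple tabular and JCAMP-DX spectra,
    and a synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
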