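Package: fibriltherm
Title: Thermodynamic and Biophysical Analysis of Amyloid Fibrillization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of protein self-association and amyloid
    fibrillization from standard biophysical assays. Inverts dynamic
    light-scattering autocorrelation traces to hydrodynamic radii and
    calibrated molecular masses, estimates the critical concentration and the
    thermodynamic state of fibril elongation under the one-dimensional
    crystallization model (free energy, enthalpy from isothermal titration
    calorimetry thermograms, entropy via Gibbs-Helmholtz, two-phase heat
    capacity), analyses water-edited solid-state NMR magnetization build-up
    curves to yield volume-to-surface ratios and fibril core diameters,
    classifies secondary structure from backbone carbon chemical shifts, fits
    Hill binding isotherms from surface plasmon resonance equilibrium
    responses with a formal cooperativity test, and extracts descriptors from
    thioflavin-T aggregation kinetics and circular dichroism spectra. A
    synthetic-data generator with known ground truth and explicit noise
    models makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
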