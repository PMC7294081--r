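Package: fluordyn
Title: 19F NMR Relaxation Dispersion and Spectral Analysis of Protein
    Conformational Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing protein conformational equilibria with
    one-dimensional 19F NMR of 5-fluorotryptophan-labeled proteins. Provides
    synthesis and processing of 1D 19F spectra (Lorentzian simulation, peak
    picking, lineshape fitting, wild-type versus mutant difference
    assignment), T1 inversion-recovery and T2 CPMG-decay fitting, global
    two-field CPMG relaxation-dispersion fitting to a two-state
    fast-exchange (Luz-Meiboom) model with chi-square profiling, a numerical
    Bloch-McConnell simulator used as an internal oracle, and structural
    comparison metrics (Kabsch superposition RMSD, active-site aperture
    distance, fluorine-label verification) for PDB models of trypsin-fold
    proteases such as thrombin and its zymogen precursor prethrombin-2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
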