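# fluordyn

Analysis of protein conformational equilibria by one-dimensional ¹⁹F NMR of
5-fluoro-tryptophan–labeled proteins. The motivating system is the clotting
protease thrombin and its zymogen precursor prethrombin-2, whose nine Trp
residues each carry one ¹⁹F reporter: the package synthesizes and processes
their 1D spectra, assigns resonances by Trp→Phe mutant difference
spectroscopy, fits T1/T2 relaxation, and extracts conformational-exchange
rates by global two-field CPMG relaxation-dispersion fitting. A structural
side module computes superposition RMSDs, the active-site aperture distance,
and fluorine-label verification from PDB models.

## The model at the core

A reporter exchanging between two environments A ⇌ B contributes an
exchange term to its effective transverse relaxation rate under a CPMG
pulse train. In the fast-exchange limit (k_ex ≫ Δω) the dispersion follows
the Luz–Meiboom closed form

    R₂,eff(ν_cpmg) = R₂⁰ + (Φ_ex / k_ex) · [ 1 − (4ν_cpmg / k_ex) · tanh( k_ex / 4ν_cpmg ) ]

with ν_cpmg = 1/(4τ_cp), Φ_ex = p_A p_B Δω² (rad²/s², scaling with the
square of the static field), and a per-field plateau R₂⁰. Only k_ex, Φ_ex
and R₂⁰ are identifiable in this regime — populations and Δω are not
separately recoverable, and the package never reports them individually.
Curves recorded at two fields (564.686 and 658.780 MHz ¹⁹F) are fitted
jointly: one shared k_ex, one R₂⁰ per field, and Φ_ex tied across fields by
the squared field ratio. The fit is validated against a numerical
Bloch–McConnell propagator (`bloch_mcconnell_r2eff()`) that evolves the
two-site transverse magnetization through every τ_cp–180°–τ_cp block with
no timescale approximation.

## Worked example

Generate a synthetic two-field dispersion dataset for the prethrombin-2
Trp51 parameter set (k_ex = 2970 s⁻¹, R₂⁰ = 204 / 260 s⁻¹, duplicate
acquisitions, 1% noise) and fit it globally:

```r
library(fluordyn)
curves <- generate_dispersion_dataset("prethrombin2_W51", noise_frac = 0.01, seed = 1)
fit <- fit_dispersion_global(curves)
fit
#> Global fast-exchange dispersion fit
#>   kex        = 3013.81 +/- 74.4 1/s
#>   phi_ex     = 308791 +/- 7.76e+03 1/s^2 (at 564.686 MHz)
#>   R2^0(564.686)   = 203.024 1/s
#>   R2^0(658.780)   = 260.097 1/s
#>   chi2 = 39.45 (reduced 0.8967, dof 44), converged: TRUE
profile_uncertainty(fit, curves, "kex", span = 1.5)
#> chi-square profile of kex: optimum 3013.81, 68.3% CI [2943.73, 3085.73]
```

The fitted rate recovers the generating 2970 s⁻¹ within its uncertainty
(the χ² profile interval and the covariance standard error agree, as they
should in a quadratic basin), and the per-field plateaus land on 204/260
s⁻¹ to a fraction of a percent.

Spectra work the same way. The thrombin reference shift list yields a
spectrum with seven resolved peaks; the most downfield one, at −43.5 ppm,
is the protease-specific Trp141 resonance absent in the zymogen:

```r
sp <- simulate_spectrum(peak_list(
        unlist(assignment_shifts(build_table2_fixture(), "thrombin")),
        fwhm_hz = 0.08 * 658.78 - 20), noise_sigma = 0)
pick_peaks(sp, threshold_frac = 0.01)
#>   center_ppm  fwhm_hz amplitude
#> 1  -43.50021 52.73600  1.000544
#> 2  -46.69963 52.99639  1.005276
#> ...                      (7 rows)
```

An end-to-end synthetic study (panels for both proteins, difference
assignment, dispersion and relaxation fits, all artifacts and a structured
run log written to disk, byte-reproducible from the seed) runs via
`run_study("out", seed = 1)` or the wrapper script
`inst/cli/fluordyn.R run-all --seed 1 --out out`.

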