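---
title: "Models and methods in fluordyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fluordyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluordyn)
```

fluordyn analyzes one-dimensional ¹⁹F NMR of proteins labeled with
5-fluoro-tryptophan — one fluorine reporter per Trp residue, no background
signal. Its motivating system is thrombin and its zymogen precursor
prethrombin-2, where the nine Trp reporters probe the equilibrium between
open (E) and collapsed (E*) active-site conformations. This vignette
documents the models, the tunable parameters, the synthetic data the
package generates for itself, and the numerical decisions taken where the
design was genuinely open.

## Two-site exchange under CPMG

A nucleus exchanging between environments A and B (populations $p_A$,
$p_B$; shift separation $\Delta\omega = 2\pi\,f_{\mathrm{MHz}}\,
\Delta\delta_{\mathrm{ppm}}$ rad/s; rate $k_{ex} = k_{AB} + k_{BA}$)
relaxes faster than either pure state while a CPMG train refocuses only
part of the exchange broadening. In the fast-exchange limit
($k_{ex} \gg \Delta\omega$) the measurable dispersion collapses to the
Luz–Meiboom form

$$R_{2,\mathrm{eff}}(\nu) = R_2^0 + \frac{\Phi_{ex}}{k_{ex}}
  \left[1 - \frac{4\nu}{k_{ex}}\tanh\frac{k_{ex}}{4\nu}\right],
  \qquad \Phi_{ex} = p_A p_B \Delta\omega^2 .$$

Assumptions: exactly two sites, first-order exchange, ideal 180° pulses,
no scalar coupling or off-resonance effects (nothing in the data
constrains them), and fast exchange for the user-facing fit. The model is
monotone non-increasing in $\nu$, from $R_2^0 + \Phi_{ex}/k_{ex}$ down to
$R_2^0$.

**CPMG frequency convention.** Throughout the package
$\nu_{cpmg} = 1/(4\tau_{cp})$, where $2\tau_{cp}$ is the delay between
successive 180° pulses. Conventions differ between labs by a factor of
two; every fitted $k_{ex}$ is tied to this declaration. The number of
pulses in a constant-time period is $n = 2\,t_{relax}\,\nu_{cpmg}$,
rounded to a positive even integer so the train ends refocused, and the
realized $\tau_{cp} = t_{relax}/(2n)$ keeps the total time exact.

**Identifiability.** Fast exchange determines only $k_{ex}$, $\Phi_{ex}$
and the per-field plateau $R_2^0$. The populations and $\Delta\omega$
enter solely through their product $\Phi_{ex}$ and cannot be separated;
the package deliberately offers no interface that reports them
individually. $\Phi_{ex}$ scales with the square of the static field,
which is what makes two-field data decisive: the global fit shares
$k_{ex}$, gives each field its own $R_2^0$, and ties $\Phi_{ex}$ across
fields by $(f/f_{ref})^2$. The reference field is a pure
reparameterization (verified to $10^{-8}$ in the tests).

## The Bloch–McConnell oracle

`bloch_mcconnell_r2eff()` makes no timescale approximation: it propagates
the two transverse coherences $(M_A^+, M_B^+)$ through each
$\tau_{cp}$–180°–$\tau_{cp}$ block under the 2×2 complex Liouvillian
(offsets $\pm\Delta\omega/2$, per-state relaxation, exchange
$k_{AB} = p_B k_{ex}$, $k_{BA} = p_A k_{ex}$), with ideal 180° pulses as
complex conjugation and matrix exponentials per block (eigendecomposition;
the matrices are 2×2, so this is exact and cheap). The detected amplitude
is $|M_A + M_B|$ after the train; with an even pulse count the residual
phase is negligible. $R_{2,\mathrm{eff}} = -\ln(I/I_0)/t_{relax}$ with
$t_{relax} = 0.04$ s by default; points whose surviving signal underflows
$10^{-12}$ are flagged rather than silently reported.

The oracle is used to *quantify* the closed form's approximation error,
never to correct it: across 100 random parameter sets with
$k_{ex}/\Delta\omega \ge 10$ the two routes agree within 2% (a test and an
acceptance check). Carver–Richards all-timescale fitting is deliberately
not a user-facing mode — the data this package targets are fit in the
fast-exchange regime, and offering a more general model the data cannot
constrain invites over-interpretation.

## Global dispersion fitting

`fit_dispersion_global()` minimizes weighted least squares
(weights $1/\sigma^2$ when uncertainties are present, unweighted
otherwise) by Levenberg–Marquardt. Two structural facts shape the
implementation:

* For fixed $k_{ex}$ the model is *linear* in $\Phi_{ex}$ and the
  $R_2^0$'s, so each multistart solves those exactly by weighted linear
  least squares before the joint refinement. Noiseless round trips
  therefore recover generating parameters to machine precision.
* The $\chi^2$ surface in $k_{ex}$ can be flat or multimodal when the
  dispersion is weak, so the fit multistarts from a log-spaced $k_{ex}$
  grid spanning $10^2$–$10^6$ s⁻¹ (9 starts), keeps the lowest $\chi^2$,
  and breaks ties ($\Delta\chi^2 < 10^{-6}$) toward smaller $k_{ex}$ —
  the conservative choice, since an unconstrained rate should not be
  inflated.

Standard errors come from the covariance at the optimum, inverted by SVD
pseudo-inverse: near-degenerate Hessians are a *physical* situation here
(no dispersion ⇒ $k_{ex}$ unconstrained), not a numerical accident, and a
hard `solve()` would fail exactly when the flags matter most. When the
fitted amplitude $\Phi_{ex}/k_{ex}$ falls below twice the median point
uncertainty the result carries a `"no dispersion"` flag and $k_{ex}$ must
be read as unconstrained. `profile_uncertainty()` complements the
covariance errors with a 1-D $\chi^2$ profile (others re-optimized;
68.3% interval at $\Delta\chi^2 = 1$, rescaled by the residual variance
for unweighted fits); in a quadratic basin the two agree within 10%,
and a divergent profile is the honest answer for flat data.

## Spectra

Spectra live on a ppm axis referenced to TFA = 0, stored downfield →
upfield; 5-F-Trp resonances fall near −43 to −50 ppm. The default
synthetic axis is −40 to −54 ppm with $2^{14}$ points. The stated
acquisition sweep width (20,000 Hz, "42.5 ppm") is inconsistent with both
¹⁹F frequencies in use (20,000 Hz is 35.4 ppm at 564.686 MHz and 30.4 ppm
at 658.780 MHz); the fixture axis above was chosen to cover the observed
resonances with margin and does not reproduce that figure.

Simulation sums Lorentzians $A/(1 + (2(\delta-\delta_0)f/w)^2)$ with
effective width $w = \mathrm{fwhm} + \mathrm{lb}$: an ideal exponential
apodization adds its line broadening (20 Hz, the standard processing
value) to a Lorentzian's FWHM. Reference-table spectra use per-peak
widths of $0.08\,\mathrm{ppm}\cdot f - 20\,\mathrm{Hz}$ so the effective
width is 0.08 ppm — narrow enough to resolve the 0.2-ppm Trp60d doublet,
consistent with seven resolved protease peaks. Amplitudes are equimolar
(one unit per resonance): relative intensities of the real spectra are
unpublished, so this is a declared convention, and it automatically makes
the zymogen's −47.9 ppm six-residue pileup "large and broad" by
superposition. A reported peak broadening of "0.27 to 0.37 Hz" in the
source material is dimensionally implausible at these fields (almost
certainly ppm) and is hard-coded nowhere.

Peak picking takes strict local maxima above a threshold (default 1% of
the spectrum maximum), merges maxima closer than 0.05 ppm keeping the
taller, and reads FWHM from interpolated half-height crossings. A maximum
falling exactly between two grid points (a two-point plateau) is detected
once — a real tie-break, exercised by the tests.

**Difference assignment.** Trp→Phe substitution removes one residue's
resonance(s); `assign_by_difference()` reports contiguous regions where
|WT − mutant| exceeds
$\max(3\hat\sigma,\; 0.01\cdot\max|\mathrm{diff}|)$, with $\hat\sigma$
estimated from the most upfield (signal-free) tenth of the axis. The
floor term keeps the operation well-posed on noiseless synthetic spectra,
where Lorentzian tails are nonzero everywhere. Runs separated by
sub-linewidth gaps (< 0.02 ppm) are merged — a noise dip inside a genuine
region should not split it — and regions narrower than 0.02 ppm are
discarded as noise excursions. Mutant simulation removes the mutated
residue's peaks exactly by default; real mutant spectra show
non-selective perturbations, so an optional jitter mode nudges the two
nearest neighbors by up to ±0.03 ppm for robustness exercises.

## Relaxation fitting

Inversion recovery: $I(t) = I_\infty(1 - 2f e^{-t/T_1})$ on the standard
eight-delay grid (0.0625–8 s), with the inversion efficiency $f$ free in
$[0.5, 1]$ (initialized at 0.98; the acquisition details do not pin it
down, and $f = 0.5$ is the saturation-recovery limit with zero null
time). A monotone-decreasing series is rejected as a model mismatch.
CPMG decay: $I(t) = I_0 e^{-t/T_2}$ on 0.5–128 ms evolution times,
initialized log-linearly; a non-decaying series is flagged
`"non-relaxing"` rather than raised. Both fits weight by $1/\sigma$ when
uncertainties exist and are scale-equivariant; duplicate acquisitions
pooled as independent points are numerically identical to fitting
per-time means with $\sigma/\sqrt{2}$ weights (asserted in the tests).
The 7-s relaxation delay is acquisition metadata only.

## Synthetic study conditions

The generators *are* the study conditions, fixed once:

* Fields 564.686 and 658.780 MHz (the "600 MHz second field" in common
  parlance is the ¹⁹F frequency 564.686 MHz of a 600-MHz magnet).
* Exchange fixtures: the three two-field parameter sets
  (k_ex = 2970 / 7980 / 19000 s⁻¹ with plateaus 204/260, 160/258,
  100/140 s⁻¹). $\Phi_{ex}$ is not identifiable from the source data and
  is fixed at $3\times10^5$ s⁻² at 564.686 MHz, giving dispersion
  amplitudes of order $10^2$ s⁻¹, comparable to the plateaus; recovery of
  $k_{ex}$ and $R_2^0$ is independent of this choice.
* CPMG grid: 12 log-spaced points, 25–5000 Hz. The experimental pulse
  spacings (τ_cp 50–500 μs) correspond to 500–5000 Hz under the package's
  convention; the low-frequency points anchor the plateau. The upper end
  matters: a grid truncated at 2000 Hz leaves the fastest process
  (k_ex ≈ 1.9×10⁴ s⁻¹) unconstrained at realistic noise, because such a
  curve barely begins to disperse below $k_{ex}/4$ Hz.
* Noise: 1% proportional, σ recorded per point; duplicate acquisitions at
  every frequency, as collected experimentally.
* Determinism: one root seed; child seeds per file by fixed offsets. The
  full pipeline (`run_study()`) is byte-identical across reruns.

What the generator does *not* emulate: phasing and baseline artifacts of
real FIDs, intensity differences between residues, temperature drift,
scalar coupling, pulse miscalibration, and spectrometer raw formats.
Passing tests therefore demonstrate correctness of the estimators under
the declared model, not robustness to every pathology of real data.

Problem sizes in the shipped tests: 16k-point spectra, 12-point dispersion
curves in duplicate at two fields, 20-seed calibration ensembles, and
100-parameter-set oracle sweeps — the full suite runs in well under a
minute.

## Structural metrics

`kabsch_rmsd()` pairs atoms on (chain, residue number + insertion code,
atom name) — chymotrypsin numbering with insertion codes (60D) preserved —
and solves the optimal proper rotation by SVD with reflection correction.
The default selection is Cα of common residues: the atom set behind the
published whole-model RMSDs (0.33 Å labeled vs unlabeled prethrombin-2;
0.41 Å for the thrombin·PPACK pair) is not stated, Cα is the conventional
choice, and the reproduction should be read as approximate with the
selection reported alongside. Waters are always excluded; altlocs reduce
to the highest-occupancy conformer; any Trp-derived residue name (TRP,
FTR, 4FW, …) at the nine reporter positions is treated as Trp, since
5-F-Trp naming varies across depositions. The aperture metric is the
Gly193–Gly216 Cα–Cα distance (≈12 Å open/E vs 8.1 Å collapsed/E*);
models are tagged E-like at or above the 10-Å midpoint. These
comparisons need the deposited coordinate files (6V5T, 6V64, 3SQH, 1PPB),
which are not shipped; the test suite exercises the machinery on models
constructed in code, including a brute-force rigid-motion oracle.

## Known limitations

* Fast-exchange-only fitting: rates below ≈10× the shift separation bias
  the closed form; the oracle quantifies but does not correct this.
* Wald (covariance) errors undercover in strongly curved basins — the
  χ² profile is the better interval when it matters.
* Mono-exponential relaxation only; multi-exponential decomposition and
  ≥3-site exchange are out of scope.
* The equimolar-amplitude convention makes synthetic peak-height ratios
  uninformative about the real system.
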