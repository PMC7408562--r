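---
title: "Models and methods: spectroscopic analysis of drug-plasma and drug-membrane binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: spectroscopic analysis of drug-plasma and drug-membrane binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrobind)
```

spectrobind implements the complete quantitative chain used to characterize
a chromophoric drug's interactions with blood components by absorption and
fluorescence spectroscopy. This vignette is the package's account of the
underlying models, the assumptions each fit makes, the numerical choices,
and what the synthetic-data generators do and do not emulate. The running
example is temozolomide (TMZ) binding to human serum albumin (HSA),
alpha-1-acid glycoprotein (AGP) and phosphatidylcholine vesicles, but
nothing in the code is specific to that system.

Units are fixed package-wide: wavelengths in nm, molar extinction in
M⁻¹ cm⁻¹, concentrations in M, energies in J mol⁻¹, time in hours.
Temperatures are supplied in °C at interfaces and converted internally to
K (the gas constant is R = 8.3145 J mol⁻¹ K⁻¹).

## Spectra

A `spectrum()` is a tibble of strictly increasing wavelengths with one
signal column plus a kind tag (absorbance, emission, extinction). Three
numerical decisions matter:

* **Integration** (`band_area()`) is the trapezoid rule on the native grid,
  with the integration limits honoured exactly by linear interpolation when
  they fall between grid points. Trapezoid on tabulated data is the field
  standard and is easy to check against closed-form Gaussian areas; the
  test suite does exactly that. Emission intensities are integrated raw —
  no pre-smoothing — because smoothing before integration changes nothing
  to first order but would add a hidden parameter.
* **Interpolation** (`resample()`) is linear only and refuses to
  extrapolate: the band shape outside the measured range is unknown and
  inventing it would silently corrupt overlap integrals.
* **The second derivative** (`second_derivative()`) is a sliding local
  quadratic least-squares (Savitzky–Golay-type) differentiator. It is
  written directly on the wavelength values so unevenly spaced grids are
  handled, and the window slides one-sided at the edges so the output grid
  equals the input grid. The window (default 7 points, odd, ≥ 5) trades
  noise suppression against band distortion; 7 points on a 1 nm grid
  distorts a 10 nm-wide band by well under 1%. Uniform-grid output is
  cross-checked against `signal::sgolayfilt()` in the tests. Second
  derivatives of degree-≤2 polynomials are reproduced exactly, which is the
  property the tests pin.

The inner-filter correction `inner_filter_correct()` is the standard
multiplicative form I_cor = I_obs·10^((A_ex+A_em)/2), where the absorbances
are the *differences* caused by ligand addition at the excitation and
emission wavelengths. It applies element-wise when A_em varies across an
emission spectrum. The correction assumes a centred 1 cm excitation
geometry; no scattering or baseline correction is attempted (vesicle blanks
are subtracted upstream by the caller).

## Quenching and binding

`fit_stern_volmer()` fits I₀/I = 1 + K_SV[Q] by ordinary least squares.
I₀ is by convention the intensity of the zero-quencher point (averaged if
replicated); the intercept is reported as a diagnostic and should be ≈ 1.
A negative fitted slope is flagged `non_quenching` rather than raised as an
error, because a flat titration is a legitimate experimental outcome.
`bimolecular_rate_constant()` divides K_SV by the unquenched lifetime
(default τ₀ = 6.4 ns, the accepted average integral lifetime of protein
tryptophan), and `classify_quenching()` applies the usual diagnostic: an
apparent k_q above the diffusion-collision ceiling of 2.0×10¹⁰ M⁻¹ s⁻¹
(strict inequality) cannot be collisional, so the quenching is static —
i.e. a ground-state complex forms.

`fit_binding_isotherm()` fits the 1:1 saturation model
ΔI = (I₀ − I_c)[L]/(1/K_a + [L]). Its assumptions are explicit:

* one binding site (or several of indistinguishable affinity);
* ligand in large excess over protein, so the free ligand concentration
  equals the added concentration (no depletion correction);
* I_c, the fluorescence of the fully complexed protein, constant and
  bounded to [0, I₀].

The optimiser is bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) started
from a double-reciprocal linearization, with up to five restarts from
log-normally jittered starts; K-type parameters are bounded to
[10⁻⁶, 10¹²] because extreme bounds destabilise the underlying MINPACK
scaling. The same fitting contract is used by every nonlinear fit in the
package. Requiring ≥ 4 concentrations spanning at least a factor of five
rejects titrations that cannot constrain a hyperbola.

Thermodynamics: `gibbs_free_energy()` is −RT ln K_a (reference temperature
298.15 K when unstated). `vant_hoff()` uses the exact two-point closed form
when only two temperatures are available — the common experimental design,
e.g. 15 °C and 25 °C — and switches to (optionally weighted) linear
regression of ln K on 1/T for three or more. The returned parameters always
satisfy ΔG = ΔH − TΔS by construction.

## FRET geometry

`overlap_integral()` evaluates J = ∫I(λ)ε(λ)λ⁴dλ with the donor emission
normalized to unit area over its full recorded range (the range is a
parameter, default the donor's own grid, conventionally 290–400 nm for
tryptophan). Both spectra are resampled to the intersection of their ranges
at the finer of the two native steps; the choice is checked in tests
against brute-force evaluation on a 100× finer grid (agreement to 0.1%).
Disjoint spectra return J = 0 with a warning rather than an error, since
"no overlap" is a physically meaningful result.

`forster_radius()` is R₀ = 0.2108·[κ²Φ_F n⁻⁴J]^(1/6) Å for J in
M⁻¹ cm⁻¹ nm⁴. The defaults κ² = 2/3 (dynamic random orientation) and
n = 1.425 (aqueous protein solution) are defaults, not constants. With the
published inputs for the albumin pair (J = 6.68×10¹³, Φ = 0.1) the package
computes R₀ = 21.35 Å; for the glycoprotein pair (J = 7.17×10¹³, Φ = 0.07)
it computes 20.36 Å, about 1.7% below the rounded literature figure of
≈20.7 Å for the same inputs — the package reports the computed value and
makes no attempt to match rounded intermediates. `max_significant_distance()`
encodes the usual rule that transfer is significant only below 1.5·R₀. No
efficiency→distance inversion is offered: when quenching mechanisms other
than FRET contribute, that inversion is not reliable.

## Membrane partitioning

`fit_partition()` fits ΔA = ΔA_max[lipid]/(1/(K_p γ) + [lipid]) with
γ = 0.9 M⁻¹ the lipid molar volume. ΔA is defined free-state minus
observed, so it is positive when binding lowers the extinction coefficient.
Two modes reflect a real identifiability problem. When the titration does
not approach saturation, ΔA_max and K_p are nearly collinear; fixing
ΔA_max from an independent estimate of the bound-state extinction
(`fixed_bound`) resolves K_p, while floating it (`free_bound`) typically
inflates the K_p standard error so much that only an upper bound is
defensible. The fit makes that explicit: in free mode a relative standard
error above 50% sets `upper_bound_flag`. The threshold is a package choice;
it reproduces qualitatively the situation where a fixed-plateau fit gives
K_p ≈ 159 ± 10 but the free fit can only bound K_p below ~1000. Callers may
pass ΔA computed from second-derivative amplitudes instead of raw
absorbances; the fit is identical because the derivative is linear in the
signal.

## Anisotropy and the lipid phase transition

`steady_state_anisotropy()` implements ⟨r⟩ = (I_VV − G·I_VH)/(I_VV + 2G·I_VH)
with G = I_HV/I_HH; G defaults to 1 because many instruments pre-correct
the transmissivity bias. The gel→fluid transition of a probe-labelled
bilayer is fitted by `fit_thermotropic_transition()` with a four-parameter
logistic r(T) = r_high + (r_low − r_high)/(1 + exp((T − T_m)/w)). The
logistic form is a package choice (experimental curves are usually judged
by eye); it is recorded in the result's `model` field. Two degeneracy
guards reject curves with no detectable transition: a fitted amplitude
below three residual standard deviations, and a fitted midpoint outside
the measured temperature window (a "transition" the data never crossed).

## Degradation kinetics

The hydrolytic decomposition of the prodrug is tracked as the normalized
absorbance of its main band over time. `fit_first_order_decay()` fits
A(t) = A_∞ + (A₀ − A_∞)e^(−kt); the single-exponential envelope is a
package modelling decision — the underlying chemistry is a two-step
cascade (prodrug → ring-opened intermediate → final product), but the
observable band decay is mono-exponential to the precision of these
measurements and the literature half-lives (≈1.8 h in plasma, ≈1 h in
buffer at 37 °C) presuppose it. The plateau is fixed at zero unless
`fit_plateau = TRUE`. A series whose overall trend is non-decreasing is
rejected as model mismatch rather than silently returning k ≈ 0.
`compare_decay()` fits a list of conditions and reports whether the rates
decrease strictly along the supplied order, the expected signature when
increasing protein concentration shields the hydrolysable group.

## Plasma distribution

`bound_fractions()` solves the competitive single-site equilibrium. The
default mode neglects drug depletion (each protein far exceeds the bound
drug), giving the closed form f_i = K_a,i[P_i]/(1 + Σ K_a,j[P_j]); with
physiological inputs (albumin 600 µM with K_a = 4016 M⁻¹; glycoprotein
15 µM — the midpoint of the healthy 10–20 µM range — with K_a = 8184 M⁻¹)
the albumin-bound fraction is 68.2% and the glycoprotein-bound fraction
3.5%. Glycoprotein figures quoted in the literature for this system
(≈2%) depend on which concentration in the healthy range is assumed; the
package computes fractions for user-stated inputs and takes no side. The
optional mass-balance mode solves the coupled equilibria for the free-drug
concentration by bisection (200 halvings of [0, drug_conc], i.e. converged
to machine precision) and reduces to the closed form in the trace-drug
limit, which the tests verify. One independent site per protein is assumed
throughout, consistent with the 1:1 isotherm. Erythrocyte membranes are
deliberately absent from the distribution model: with K_p of order 10²,
lipid binding at physiological lipid concentrations is negligible.

## Synthetic data

The `sim_*()` generators produce every input class the analyses consume,
under the conditions the real experiments used:

* emission band peaking at 334 nm on a 290–400 nm grid (protein
  tryptophan), Gaussian in wavelength;
* drug absorbance with a 329 nm major and 258 nm minor band converting to
  a single 265 nm product band as the degraded fraction goes 0 → 1;
* quenching titrations from the Stern–Volmer (K_SV = 4837 M⁻¹ scale,
  0–55 µM quencher) and isotherm forward models;
* partition titrations from the saturation model (K_p ≈ 159, γ = 0.9,
  lipid 0–3 mM);
* polarized-intensity series encoding a sigmoidal anisotropy drop between
  plateaus 0.339 and 0.092 around 23 °C, obtained by inverting the
  anisotropy relation at unit total intensity;
* first-order decay series (k = 0.385 h⁻¹ ↔ t₁/₂ = 1.8 h scale).

Noise is additive Gaussian with a standard deviation stated relative to
each model's dynamic range — a reasonable emulation of photometric noise
at these signal levels that keeps recovery statistics tractable. Seeds are
mandatory for noisy generation, there is no hidden RNG state (the global
stream is left untouched), and identical seed + parameters give
bit-identical output. The generators use ideal Gaussian bands and exact
forward models: they do not emulate instrument-response convolution,
Raman/scatter artifacts, asymmetric band shapes, or wavelength-dependent
detector sensitivity. Passing recovery tests therefore demonstrates the
correctness of the fitting code under the stated statistical assumptions,
not robustness to systematic instrumental error.

Every generator/fit pair inverts exactly (to 10⁻⁶ relative) at zero noise;
this round-trip property is the backbone of the test suite. Monte-Carlo
recovery checks use 200 replicates where a claim is about a median (a few
seconds each at these problem sizes: 8–20 points per titration) and 25–60
replicates for auxiliary mean-recovery checks.

## Known limitations

* The quencher/ligand concentration is taken as the total added
  concentration; systems where the protein is not in excess need the
  mass-balance machinery, which is only implemented for the distribution
  calculation, not for the isotherm fit.
* No Hill/multi-site or cooperative binding models.
* No time-resolved anisotropy or order-parameter modelling; the logistic
  transition fit locates T_m but its width parameter is an empirical
  sharpness, not a thermodynamic cooperativity.
* The decay model is the observable envelope only; no mechanistic
  multi-step kinetic network.
* Circular dichroism, docking and molecular-dynamics analyses that often
  accompany these experiments are out of scope.
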