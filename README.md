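# spectrobind

Quantitative analysis of the spectroscopic experiments used to characterize
how a small-molecule drug distributes among blood components: binding to the
plasma proteins human serum albumin (HSA) and alpha-1-acid glycoprotein
(AGP), partitioning into lipid-vesicle model membranes, and the hydrolytic
stability of the free versus protein-bound drug. The motivating system is
temozolomide (TMZ), the alkylating prodrug used against glioblastoma, whose
short plasma half-life and weak protein binding make these measurements
central to any delivery strategy — but every routine is generic over
drug/protein/lipid systems measured the same way.

The package is tidyverse-native: titrations and spectra are tibbles, every
fit returns an S3 object with broom-style `tidy()`/`glance()` methods and a
ggplot2 `autoplot()`, and seeded `sim_*()` generators emulate each
experiment class so every analysis is testable without instrument data.

## What it computes

**Fluorescence quenching and binding.** Protein emission spectra (excitation
280 nm, emission 290–400 nm) are corrected for the inner filter effect,
I<sub>cor</sub> = I<sub>obs</sub>·10^((A_ex + A_em)/2), and integrated with
`band_area()`. Quenching titrations are analysed two ways:

- Stern–Volmer: I₀/I = 1 + K_SV·[Q]; `fit_stern_volmer()` returns K_SV, and
  `bimolecular_rate_constant()` gives k_q = K_SV/τ₀ (τ₀ = 6.4 ns for protein
  tryptophan). `classify_quenching()` labels k_q above the diffusion limit
  (2×10¹⁰ M⁻¹s⁻¹) as static quenching.
- 1:1 binding isotherm: ΔI = (I₀ − I_c)·[L]/(1/K_a + [L]);
  `fit_binding_isotherm()` returns K_a (and K_d = 1/K_a), with
  `gibbs_free_energy()` (ΔG = −RT ln K_a) and `vant_hoff()` (ΔH, ΔS) for the
  thermodynamics.

**FRET geometry.** `overlap_integral()` computes
J = ∫I(λ)ε(λ)λ⁴dλ with the donor emission area-normalized;
`forster_radius()` evaluates R₀ = 0.2108·[κ²·Φ_F·n⁻⁴·J]^(1/6) Å and
`max_significant_distance()` the 1.5·R₀ bound on the donor–acceptor
distance.

**Membrane partitioning.** `fit_partition()` fits
ΔA = ΔA_max·[lipid]/(1/(K_p·γ) + [lipid]) (γ = 0.9 M⁻¹ lipid molar volume)
in a fixed- or free-plateau mode, flagging unidentifiable K_p;
`lipid_bound_fraction()` converts K_p to a bound fraction.

**Anisotropy and phase transitions.** `steady_state_anisotropy()` implements
⟨r⟩ = (I_VV − G·I_VH)/(I_VV + 2G·I_VH) with `g_factor()` for the instrument
correction; `fit_thermotropic_transition()` locates the lipid gel→fluid
transition from the sigmoidal anisotropy drop.

**Stability kinetics.** `fit_first_order_decay()` fits
A(t) = A_∞ + (A₀ − A_∞)e^(−kt) to degradation time courses and reports
t₁/₂ = ln 2/k; `compare_decay()` orders conditions by rate.

**Plasma distribution.** `bound_fractions()` computes the competitive
single-site equilibrium split of the drug among plasma proteins,
f_i = K_a,i[P_i]/(1 + Σ_j K_a,j[P_j]), with an optional mass-balance mode
for finite drug concentration.

## Worked example

```r
library(spectrobind)

# a quenching titration at 25 °C: 12 ligand concentrations, 1% noise
titr <- sim_quench_titration("isotherm", list(K_a = 5103, I0 = 1, Ic = 0),
                             conc_grid = seq(0, 4e-4, length.out = 12),
                             noise = noise_spec("gaussian", 0.01, seed = 42))
fit <- fit_binding_isotherm(titr)
fit
#> 1:1 binding fit: K_a = 5783 +/- 2.7e+02 M^-1 (K_d = 0.000173 M), Ic/I0 = 0.055
tidy(fit)
#> # A tibble: 2 × 3
#>   term   estimate std.error
#>   <chr>     <dbl>     <dbl>
#> 1 K_a   5783.      267.
#> 2 Ic       0.0560    0.0186
gibbs_free_energy(fit$K_a, 298.15)
#> [1] -21474.64
```

The fitted K_a of 5783 ± 270 M⁻¹ sits within noise of the generating value
5103 M⁻¹ (a sub-millimolar K_d: moderate, reversible binding), and the
corresponding ΔG ≈ −21.5 kJ mol⁻¹ confirms a spontaneous association. The
competitive plasma split for albumin (600 µM, K_a 4016 M⁻¹) against the
glycoprotein (15 µM, K_a 8184 M⁻¹):

```r
bound_fractions(plasma_composition(c("HSA", "AGP"),
                                   c(4016, 8184), c(600e-6, 15e-6)))
#> # A tibble: 3 × 2
#>   name  fraction
#>   <chr>    <dbl>
#> 1 HSA     0.682
#> 2 AGP     0.0348
#> 3 free    0.283
```

— about 68% of the circulating drug rides on albumin despite the
glycoprotein's higher affinity, because albumin is ~40-fold more
concentrated.

A thin command-line wrapper (`inst/cli/spectrobind`, or `run_cli()` from R)
exposes the same operations as subcommands (`fit-sv`, `fit-ka`, `fret`,
`fit-kp`, `fit-transition`, `decay`, `plasma-fraction`, `simulate`, ...);
every output file echoes its full configuration in `#` header lines.

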