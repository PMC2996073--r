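---
title: "Methods: simultaneous-equation UV quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous-equation UV quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vierordt)
```

## The model

The package quantifies n-component drug mixtures from UV absorbance
readings at n analytical wavelengths. Its physical model is the
Beer–Lambert law with additivity: at wavelength $\lambda_i$ the measured
absorbance of a mixture in a 1 cm cell is

$$A_i = \sum_j a_{ij} \, C_j,$$

where $a_{ij}$ is the specific absorptivity of component $j$ at
$\lambda_i$ in $A(1\,\mathrm{g}/100\,\mathrm{ml},\,1\,\mathrm{cm})$ units
and $C_j$ is the concentration in g/100 ml (the solver's internal unit;
results are also reported in µg/ml, 1 g/100 ml = $10^4$ µg/ml).
Readings at pathlengths other than 1 cm are divided by the pathlength
before solving.

For two components the closed form (`solve_two_component()`) is
Cramer's rule written with reversed numerators over the signed
denominator $D = -(a_{11}a_{22} - a_{12}a_{21})$:

$$C_1 = \frac{A_2 a_{12} - A_1 a_{22}}{D}, \qquad
  C_2 = \frac{A_1 a_{21} - A_2 a_{11}}{D}.$$

This is algebraically identical to textbook Cramer's rule; the package
keeps the signed-denominator convention because the shipped presets'
denominators (−116494.95 for LOK/ATL, −487532 for ATL/HCTZ) are
conventionally quoted in this form, and `vierordt_denominator()`
reproduces them. `solve_general()` solves the same system for any n by
LU factorization (base `solve()`); the two routes agree to about 1e−9
relative on 2×2 systems and are tested against each other.

### Assumptions

* Linearity: each analyte obeys Beer's law over its calibration range
  (LOK 5–30, ATL 2–12, HCTZ 2–14 µg/ml in the presets). Solved
  concentrations can be checked against fitted curves with
  `flag_beers_range()`, which warns rather than refuses.
* Additivity: no chemical interaction or spectral shift between
  components; excipients do not absorb at the analytical wavelengths.
* The absorptivity matrix applies to the sample's solvent and
  instrument. The two presets carry different ATL absorptivities at
  224.20 nm (380.50 vs 866.75) because they were determined against
  different partners and dilution series; the package deliberately keeps
  each system's own values and never mixes them.

### Numerical choices

* Negative solved concentrations are returned and flagged
  (`negative_concentration`), never clamped: clamping would hide
  calibration or matrix errors.
* A system is declared singular when $|\det M| < 10^{-12} \prod_i
  \max_j |a_{ij}|$ (scale-invariant absolute tolerance).
* `condition_diagnostics()` reports the exact 2-norm condition number
  with advisory levels ok (< 1e3), warn ([1e3, 1e8)) and error (≥ 1e8 or
  singular). Both presets sit well inside "ok" (≈ 5.7 and ≈ 5.9).

## Spectra

`uv_spectrum` stores the wavelength grid exactly as given (no resampling
on read) over a configurable instrument range defaulting to 200–400 nm.
`absorbance_at()` interpolates linearly: the method only reads
absorbances at fixed analytical wavelengths, and linear interpolation is
transparent, monotone between grid points, and exact on grid hits.
`find_lambda_max()` takes the discrete maximum (first index on ties,
i.e. the lower wavelength) and refines it with the three-point parabolic
vertex formula; an exact plateau or a maximum on the window edge is
returned unrefined, and a flat spectrum is an error rather than an
arbitrary answer.

## Calibration

`fit_beers_law()` is ordinary least squares of absorbance on
concentration with a fitted (never forced) intercept, reporting the
Pearson r — not r² — and the concentration span as the validity range.
`mean_absorptivity()` averages $A/c$ over replicate dilutions with the
$10^4$ unit conversion; on noiseless zero-intercept data it equals the
fitted slope × $10^4$, a unit-consistency property the tests enforce.
Note that absorptivities derived from the preset calibration slopes
(e.g. ATL 0.08503 × 10⁴ = 850.3) differ by a few percent from the preset
matrix coefficients (866.75): the matrix coefficients come from separate
six-dilution determinations whose raw data are not available, so both
sets are kept as published and neither is adjusted to match the other.

## The synthetic-data generator

`preset_band_models()` emulates each pure component as a sum of 2–3
Gaussian bands,
$a(\lambda) = \sum_k h_k \exp\{-(\lambda-c_k)^2/2w_k^2\}$.
Band centers and widths are fixed constants chosen so each analyte's
analytical band peaks at its published maximum (LOK 251.6, ATL 224.2,
HCTZ 271.6 nm); the heights $h_k$ are then obtained by solving the
linear system that makes the summed profile hit the published
absorptivity coefficients exactly at the analytical wavelengths. Only
those three-wavelength anchors are published, so the full curve shape is
an emulation, not a reconstruction: between anchors the simulated
spectra are plausible but arbitrary.

Because ATL's published absorptivity at 224.20 nm differs between the
two systems, the generator targets the system under test: the LOK/ATL
scenario uses an ATL model consistent with 380.50 and the ATL/HCTZ
scenario one consistent with 866.75 (`atl_variant` argument). This keeps
each preset's simulate→solve round trip exact and surfaces the published
conflict instead of averaging it away.

Simulation parameters, with defaults:

| parameter | default | why |
|---|---|---|
| grid spacing | 0.2 nm over 200–400 nm | typical slow-scan resolution of a double-beam instrument; fine enough that linear interpolation at the analytical wavelengths errs < 1e−4 AU |
| noise sd | 0.002 AU, iid Gaussian per reading | gives recovery/assay %RSDs of the order routinely reported for this kind of method (a fraction of a percent to ~2%) |
| pathlength | 1 cm | standard quartz cell |
| excipient baseline | none | the method assumes non-absorbing excipients; a baseline can be added externally for stress tests |

All generators take a `noise_model(sd, seed)`; with a seed they are
exactly reproducible and restore the ambient RNG state.

### Study designs

`generate_recovery_experiment()` reproduces the standard three-level
(80/100/120%) triplicate spiking design: base working solutions of
20/20 µg/ml (LOK/ATL) or 8/2 µg/ml (ATL/HCTZ), paired unspiked and
spiked measurements per replicate, recovery computed increment-over-added:
$100\,(\text{found}_{spiked} - \text{found}_{unspiked})/\text{added}$.
This standard-addition formula is the conventional reading of spiking a
preanalyzed sample; a total-found-over-expected convention would give
smaller RSDs at low added amounts, and the choice matters for HCTZ
(added 1.6–2.4 µg/ml), where error propagation through the solver
($\sigma_C \approx \sqrt{106^2+866.75^2}\,\sigma_A/487532 \approx
0.036$ µg/ml at $\sigma_A = 0.002$ AU) predicts within-run recovery
RSDs of ≈ 2–3% at the two lower spike levels — larger than for any
other analyte/level, and the one place where the simulated envelope is
materially wider than historically reported values.

`generate_assay_samples()` emulates the tablet assay: powder equivalent
to one tablet (50 mg of the leading drug) into a 100 ml stock, diluted
25× (LOK/ATL, to 20/20 µg/ml) or 62.5× (ATL/HCTZ, to 8/2 µg/ml), n = 5
replicates; `assay_tablets()` back-calculates mg/tablet through the
dilution chain. With zero noise the chain returns the label claims
(50/50 and 50/12.5 mg) exactly — a self-consistency identity the
acceptance tests assert at 1e−10 relative.

`precision_study()` summarizes repeatability (one-session %RSD, n = 5),
intra-day precision (the (min, max) range of per-day RSDs across days
and levels), inter-day precision (RSD across day means per level —
day means, not pooled replicates, the standard intermediate-precision
convention) and ruggedness (per-analyst RSDs). All RSDs use the sample
(n−1) standard deviation, conventional for n = 3–5 validation work.

## What the simulations do and do not show

Problem sizes used by the test suite: 1000 random systems for the
closed-form/general-solver agreement, 100 seeded repetitions for the
recovery and parameter-recovery Monte-Carlos, n = 3–5 replicates per
simulated study. Passing tests demonstrate that the algebra, unit
handling and statistics are correct, that the pipeline is unbiased
(< 0.5% bias, < 2% concentration RSD at 0.002 AU noise across the
working ranges), and that the noiseless chain is exact. They do not
demonstrate anything about real tablets: the generator has no stray
light, baseline drift, solvent or pH effects, excipient absorbance, or
inter-day/analyst variability, and its band shapes between the anchor
wavelengths are invented. Real-instrument validation still requires the
wet-lab study the statistics here are designed to summarize.

## Known limitations

* Two-component closed form and n-component direct solve only; no
  overdetermined least-squares quantification at more wavelengths than
  components, and no derivative or chemometric (PLS/PCR) methods.
* No LOD/LOQ estimation, weighted regression or outlier rejection in
  calibration.
* CSV spectrum I/O only (no JCAMP-DX), no baseline correction or
  smoothing.
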