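# vierordt

Simultaneous-equation (Vierordt) quantification of multicomponent drug
mixtures from UV absorbance spectra, with Beer's-law calibration,
analytical method-validation statistics, and a seeded synthetic-spectrum
generator.

## The problem and the method

Fixed-dose antihypertensive combinations — losartan potassium (LOK) with
atenolol (ATL), and ATL with hydrochlorothiazide (HCTZ) — can be assayed
on an ordinary double-beam UV spectrophotometer without chromatographic
separation. Each drug absorbs at the other's analytical wavelength, so a
single reading is not enough; but absorbances are additive
(Beer–Lambert), so readings at one wavelength per component give a linear
system.

For an n-component mixture read at n wavelengths,

```
A_i = sum_j a_ij * C_j        (i = 1..n)
```

where `a_ij` is the specific absorptivity A(1 g/100 ml, 1 cm) of
component *j* at wavelength *i* and `C_j` is its concentration in
g/100 ml. For the classical two-component case the closed form is
Cramer's rule written with a signed denominator `D = -(a11*a22 -
a12*a21)`:

```
C1 = (A2*a12 - A1*a22) / D
C2 = (A1*a21 - A2*a11) / D
```

Two published systems ship as presets:

| preset     | components | wavelengths (nm) | absorptivities                    | D           |
|------------|------------|------------------|-----------------------------------|-------------|
| `lok-atl`  | LOK, ATL   | 251.60, 224.20   | [[320.25, 8.1], [661.75, 380.50]] | -116494.95  |
| `atl-hctz` | ATL, HCTZ  | 224.20, 271.60   | [[866.75, 1288], [106.0, 720]]    | -487532     |

Around the solver the package provides: spectrum I/O and lambda-max
detection (`read_spectrum`, `find_lambda_max`), Beer's-law calibration
with linearity-range enforcement (`fit_beers_law`, `check_beers_range`,
`mean_absorptivity`), validation statistics (`assay_tablets`,
`recovery_study`, `precision_study`, `percent_rsd`), and a synthetic
instrument stand-in (`preset_band_models`, `simulate_mixture_spectrum`,
`generate_recovery_experiment`, `generate_assay_samples`) whose Gaussian
band models reproduce the published absorptivity coefficients exactly at
the analytical wavelengths.

## Worked example

Solve a LOK/ATL tablet extract from its two absorbance readings:

```r
library(vierordt)
m <- vierordt_preset("lok-atl")
solve_two_component(m, c(0.6567, 2.0845))
#> <mixture_result>
#>     g/100ml ug/ml
#> LOK   0.002    20
#> ATL   0.002    20
#>   determinant 116495, condition 5.71
```

The readings 0.6567 and 2.0845 AU at 251.60 and 224.20 nm correspond to
20 µg/ml of each drug — the concentrations used for the overlay scans
that fixed the analytical wavelengths. A simulated three-level spiked
recovery study at 0.002 AU instrument noise:

```r
ex <- generate_recovery_experiment("lok-atl", noise = noise_model(0.002, seed = 42))
analyze_recovery_experiment(ex)
#>   analyte level_percent added_ug_per_ml n mean_recovery_percent rsd_percent
#> 1     LOK            80              16 3                100.36      0.3134
#> 2     ATL            80              16 3                 99.61      0.8927
#> 3     LOK           100              20 3                 99.87      0.1979
#> 4     ATL           100              20 3                100.49      0.9106
#> 5     LOK           120              24 3                 99.99      0.3727
#> 6     ATL           120              24 3                100.11      0.7216
```

Mean recoveries near 100% with sub-percent RSDs say the method returns a
known added amount accurately and precisely at 80–120% spiking. A
five-replicate tablet assay against a 50 mg label claim:

```r
rep <- analyze_assay_samples(generate_assay_samples("lok-atl",
                                                    noise = noise_model(0.002, seed = 42)))
rep$LOK
#> <assay_report> LOK (n = 5)
#>   label claim 50 mg/tab, found 50.19 mg/tab (100.37% of claim)
#>   SD 0.1193 mg/tab, %RSD 0.238
```

A shell entry point is included at `inst/scripts/vierordt`:

```sh
Rscript inst/scripts/vierordt quantify --preset lok-atl --a 0.6567 --a 2.0845 --json
```

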