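# biosorb

Kinetics and equilibrium-isotherm modelling for dye biosorption
experiments — built around the batch removal of indigo blue dye by
lyophilised *Spirulina platensis* biomass, and usable for any
adsorbate/biosorbent pair measured the same way. It is aimed at
bioprocess and bioremediation researchers who have calibration series,
concentration-vs-time courses and equilibrium points, and want fitted
rate constants, isotherm slopes and a defensible model comparison out
the other end.

## What it computes

**Quantification.** A linear optical-density standard curve
`OD = m·C + b` (fit + inversion), and the definitional quantities:
removal `D = 100(Ci − Ct)/Ci`, total adsorption `Q = Ci − Ct` (mg/L),
capacity `q = Q/B` (mg/g).

**Kinetics.** Two one-parameter rate laws fitted to pooled replicate
time courses:

- pseudo-first-order (Lagergren), `q(t) = Qe(1 − e^(−K1·t))` with the
  equilibrium capacity fixed at `Qe = 0.91·Ci` (the observed
  equilibrium removal fraction), leaving the rate `K1` (1/h) as the
  single free parameter;
- Ho second-order, `1/Ct = k2·t + 1/Ci` with the intercept pinned at
  `1/Ci`, fitted by nonlinear least squares in concentration space
  (`k2` in L/(mg·h)).

The first-order law is also derived from a radial-diffusion model of
the cylindrical filament (`J0` Bessel eigenmodes with an absorbing
boundary), whose slowest mode gives `K1 = α·γ1²`.

**Model selection.** The model selection criterion

```
MSC = ln( Σ wj (Cj − C̄)² / Σ wj (Cj − Cmj)² ) − 2λ/d
```

(larger is better), alongside RMSE and RSE.

**Isotherms.** Per temperature, the through-origin C-type line
`qe = bo·Ce` with closed-form slope `Σ(Ce·qe)/Σ(Ce²)`, SE, p-value and
uncentred R²; plus the implied equilibrium removed fraction
`bo·B/(1 + bo·B)`.

**Synthetic data.** Seeded generators emulating each experimental
design (calibration series, pH screen, time courses, isotherms) so
every estimator is validated by Monte-Carlo parameter recovery; a full
synthetic study comes from one seed (`generate_study()`,
`write_study_fixtures()`), and `run_pipeline()` orchestrates all
stages into a report with per-table CSVs and JSON.

## Worked example

```r
library(biosorb)

tc <- generate_time_course(7, ci = 50, model = "first_order", rate = 0.052)
fo <- fit_first_order(tc)
fo
#> Pseudo-first-order kinetic fit (Ci = 50 mg/L)
#>   rate constant: 0.05256 +/- 0.00115 1/h
#>   fixed Qe: 45.5 mg/L ( fraction 0.91 )
#>   residual RMSE: 0.7007  RSE: 0.7253  n = 15

compare_kinetic_models(tc, fo, fit_second_order(tc))
#> # A tibble: 2 × 8
#>   model        rate_constant rate_constant_se   msc  rmse   rse n_obs n_params
#> 1 first_order        0.0526         0.00115    6.23 0.701 0.725    15        1
#> 2 second_order       0.00178        0.0000689  5.54 0.990 1.02     15        1
#> preferred model: first_order
```

The recovered `K1 = 0.0526 ± 0.0012` 1/h sits on the generating truth
0.052; the higher MSC (6.23 vs 5.54) correctly prefers the first-order
model that generated the data. The same loop closes for isotherms:

```r
fit <- fit_linear_origin(generate_isotherm(7, b_o = 10.22, temperature_C = 50))
fit
#> Through-origin isotherm fit (50 degC)
#>   slope b_o: 10.182 +/- 0.03 L/g   p = 4.51e-10
#>   R-squared (uncentred): 1   n = 5

implied_removal_fraction(10.22)
#> [1] 0.9108734
```

A partitioning slope of 10.22 L/g at 1 g/L biomass implies 91.1%
equilibrium removal — the origin of the fixed 0.91 used in the kinetic
fits. Fits carry broom-style `tidy()`/`glance()` methods and
`autoplot()` figures; the full pipeline runs as
`run_pipeline(list(synthetic = TRUE, seed = 7, output_dir = "out"))`
or from the thin CLI in `inst/cli/biosorb.R`.

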