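# spermscaling

Comparative analysis of density-dependent sperm metabolism: do sperm in
dense ejaculates respire less per cell than sperm in dilute suspensions
(the *respiratory dilution effect*), and how badly does the literature's
habit of linearly rescaling metabolic rates to a standard sperm
concentration distort reported values if they do?

The package is aimed at comparative physiologists and meta-analysts working
with sperm (or more generally cell-suspension) respirometry. It provides:

* a validated record schema and CSV I/O for heterogeneous metabolic-rate
  compilations, with exact back-calculation of linearly standardized
  reports to the rates actually measured;
* closed-chamber respirometry processing (saturation-window filtering,
  best-local-window slope extraction, control correction, unit conversion
  to µl O₂ h⁻¹);
* the log–log density–metabolism mixed model with species random
  intercepts, likelihood-ratio/AIC interaction reduction and a Wald test of
  the scaling exponent against 1;
* log-response-ratio effect sizes and the percent-change-per-decade
  summary;
* a misestimation audit of linearly standardized rates;
* a synthetic-data generator reproducing the statistical structure of a
  literature compilation, used as the ground-truth test bed throughout.

## The model

Ejaculate-level oxygen consumption is modelled as a power law in sperm
concentration, fitted on the natural-log scale with a species random
intercept:

```
ln R_is = ln a + β ln C_is + γ·endotherm_s + u_s + ε_is,
u_s ~ N(0, σ²_sp),   ε_is ~ N(0, σ²)
```

where `R` is rate (µl O₂ h⁻¹), `C` concentration (sperm ml⁻¹) and `γ` the
thermoregulation offset. Since per-capita rate is `R/(C·V)`, the per-capita
exponent is exactly `β − 1`: `β = 1` means no density dependence (what
linear standardization assumes), `β < 1` means per-capita metabolism rises
under dilution. For `β = 0.87` a 10-fold dilution raises per-capita
metabolism by `100·(10^0.13 − 1) = 34.9%` (headline 35%), and a rate
measured at concentration `C` but linearly rescaled to `C_std` misestimates
the true rate at `C_std` by the factor `(C/C_std)^(β−1)`.

## Worked example

```r
library(spermscaling)

# a compilation-structured dataset: 198 records, 49 species,
# generative exponent 0.87, 2-fold endotherm offset
d <- generate_metabolic_dataset(generator_config(seed = 1))

# half the records get reported the way the literature reports them:
# linearly standardized to 1e8 sperm/ml
reported <- generate_standardized_reports(d, std_concentration = 1e8,
                                          fraction_standardized = 0.5,
                                          seed = 1)

# harmonize back to measured rates and fit the scaling model
harm <- harmonize_records(reported)
fit  <- fit_scaling_model(harm, model_spec(covariate = "thermoregulation"))
fit
#> Density-metabolism scaling fit (ejaculate_rate, REML)
#>   exponent beta = 0.8465 (SE 0.0170)
#>   thermoregulation effect = 0.1911 (SE 0.2759), fold = 1.211
#>   species var = 0.8506, residual var = 0.2528
#>   logLik = -213.56, AIC = 437.12, n = 198 obs / 49 species

wald_test(fit, null_value = 1)
#> Wald test vs 1: t_195 = -9.028, p = 1.697e-16 (estimate 0.8465, SE 0.0170)

pc <- per_capita_exponent(fit)
percent_change_per_decade(pc$exponent)
#> [1] 42.41   # this dataset's estimate of the per-decade increase

audit <- audit_dataset(reported, beta = fit$beta)
attr(audit, "max_fold_misestimation")
#> [1] 2.75    # worst-case factor among the 99 standardized records
```

The single-dataset exponent (0.8465) scatters around the generative 0.87
with SE ≈ 0.017; averaged over 20 replicate simulations the estimate is
0.868 (see below). The Wald test firmly rejects `β = 1`: these simulated
sperm, like real ones, are density dependent. The audit shows what linear
standardization would have done to the 99 standardized records: up to a
2.75-fold error at the extremes of the concentration range.

The worked example for a single literature record: a paper reports a
standardized rate of 1.34 µl O₂ h⁻¹ at 10⁸ sperm ml⁻¹ but measured at
3×10⁸ sperm ml⁻¹. Then

```r
back_calculate_actual_rate(1.34, 1e8, 3e8)
#> [1] 4.02
```

recovers the measured 4.02 µl O₂ h⁻¹ — the original authors' linear
transformation, run in reverse.

## Analysis workflow

`analysis/` holds numbered stage drivers, each a thin narrative script over
the package functions, writing tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | simulate the compilation + standardized reporting; harmonize |
| `02_respirometry.R` | sensor-dish traces → VO₂ for a dilution series with controls |
| `03_fit_scaling.R` | mixed-model fit, interaction reduction, Wald test |
| `04_effect_sizes.R` | per-species low-vs-high LRRs and group test |
| `05_misestimation_audit.R` | audit the standardized records against the fitted exponent |

`run_pipeline()` chains the same stages programmatically and writes a
manifest with MD5 hashes; reruns with the same seed are byte-identical.

## Record CSV schema

One row per observation; UTF-8, comma-separated, header required, `.`
decimal, scientific notation accepted.

| column | content |
|---|---|
| `species` | species label |
| `thermoregulation` | `endotherm` / `ectotherm` |
| `fertilization_mode` | `internal` / `external` |
| `diluent` | `carbohydrate_free` / `carbohydrate_containing` |
| `diluent_job` | `activator` / `extender` / `unknown` |
| `handling` | `fresh` / `cooled` / `frozen_thawed` / `unknown` |
| `concentration_sperm_per_ml` | measured concentration, > 0 (may be empty only for standardized reports) |
| `rate_ul_o2_per_h` | ejaculate-level rate, µl O₂ h⁻¹, > 0 |
| `reporting` | `actual` / `standardized` |
| `std_concentration_sperm_per_ml` | required when `reporting = standardized` |
| `assay_volume_ml` | chamber volume if known (1 ml assumed otherwise) |
| `n_replicates` | replicate count if known |
| `source` | provenance, free text |

Respirometry traces are long-format CSV: `chamber_id`, `time_min`,
`pct_air_saturation`, `is_control`.

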