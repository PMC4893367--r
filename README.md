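# probank

Simulation tools for studying what clinical oversampling does to
patient-reported-outcome (PRO) item-bank calibration.

## The problem

PRO item banks measuring quasi-traits (constructs whose items are only
informative at the severe end — depression, pain interference, fatigue) are
routinely calibrated on general-population samples *enriched* with clinical
respondents, because a general sample alone leaves the upper half of the
scale poorly measured. The default item-response-theory calibration, however,
assumes the latent trait is standard normal in the calibration sample. When
the sample is enriched, that assumption is false, and the item parameters,
the latent-trait scores, the norm-referenced T-scores and the reported
standard errors all absorb the distortion. `probank` implements the full
simulation apparatus to quantify this, for biostatisticians and
psychometricians who build or audit calibration pipelines.

## What is inside

For the graded response model (GRM), where the cumulative probability of
category *k* or higher is P_k(θ) = 1/(1 + exp(−a(θ − b_k))) with a > 0 and
b1 < b2 < b3 < b4:

* `generate_item_bank()` — 40-item, 5-category quasi-trait banks whose
  per-parameter min/mean/max match a published summary profile
  (`quasi_trait_profile()`); lossless CSV/JSON serialization
  (`write_bank()`, `read_bank()`).
* `sample_latent()` — calibration samples of n = 1500 with fixed clinical
  fractions under two population views: two distinct normals (general
  N(−2,1), clinical N(0,1)), or one standard normal split at the clinical
  cut-off Φ⁻¹(1 − prevalence) = 1.28 for 10% prevalence
  (`critical_value()`, `sampling_weights()`, `expected_counts()`).
* `simulate_responses()` — multinomial GRM response matrices.
* `fit_grm()` — a from-scratch Bock–Aitkin EM marginal-maximum-likelihood
  estimator with single-group, multi-group (free general-population mean,
  clinical mean fixed at 0, SDs fixed at 1) and case-weighted
  pseudo-likelihood modes; `marginal_loglik()` exposed separately;
  broom-style `tidy()`/`glance()` methods.
* `score_responses()` / `map_estimate()` — MAP latent-trait scoring with a
  standard-normal prior and curvature-based standard errors; finite for
  all-zero patterns; optional bounded maximum-likelihood scoring.
* `param_recovery()`, `theta_recovery()`, `t_score()` — recovery outcomes:
  per-parameter correlations and mean(true − estimate), and a 17 × 500
  latent-grid scoring study (θ from −4 to 4 by 0.5).
* `run_study()` — the full 12-condition experiment (2 scenarios × clinical
  fractions 25/50/75% × proper/improper calibration), with tidy tables
  (`item_recovery_table()`, `person_recovery_table()`, `bias_curve_table()`)
  and plots (`plot_bias_curves()`).

## Worked example

Calibrate one enriched sample (two-population scenario, 50% clinical) the
wrong way and the right way:

```r
library(probank)

bank <- generate_item_bank(n_items = 40, seed = 11)   # the generating truth
bank_summary(bank)
#> # A tibble: 5 × 4
#>   parameter   min   mean   max
#>   <chr>     <dbl>  <dbl> <dbl>
#> 1 a          1.04  1.89   2.66
#> 2 b1        -0.97 -0.110  0.89
#> 3 b2         0.27  0.901  1.52
#> 4 b3         1.22  1.94   2.72
#> 5 b4         2.2   2.95   3.57

design <- sampling_design(scenario = 1, n_total = 1500, clinical_fraction = 0.5)
samp <- sample_latent(design, seed = 4)    # 750 general N(-2,1), 750 clinical N(0,1)
resp <- simulate_responses(samp, bank, seed = 5)

improper <- fit_grm(resp)                  # pretends theta ~ N(0,1)
proper   <- fit_grm(resp, groups = samp$group,
                    group_means = c(general = NA, clinical = 0))
proper
#> GRM fit: 40 items, 1500 persons
#>   groups: general = -2.035, clinical = 0.000 (fixed)
#>   logLik -37020.49 after 197 EM cycles (converged)

param_recovery(bank, improper$bank)
#> # A tibble: 5 × 3
#>   parameter   cor mean_diff
#>   <chr>     <dbl>     <dbl>
#> 1 a         0.969    -0.757
#> 2 b1        0.996    -0.771
#> 3 b2        0.984    -0.476
#> 4 b3        0.970    -0.168
#> 5 b4        0.890     0.136

param_recovery(bank, proper$bank)
#> # A tibble: 5 × 3
#>   parameter   cor mean_diff
#>   <chr>     <dbl>     <dbl>
#> 1 a         0.969    0.0694
#> 2 b1        0.996   -0.0440
#> 3 b2        0.984   -0.0754
#> 4 b3        0.970   -0.0939
#> 5 b4        0.887   -0.105
```

Reading the numbers: both calibrations rank the items almost perfectly
(correlations ≈ 0.9–1.0), but the improper fit is biased — discriminations
are inflated by about 41% (mean a difference −0.76, because the ignored
mixture has SD ≈ √2) and the lower thresholds are shifted by about the
mixture mean. The proper multi-group fit recovers the generating parameters
(all mean differences within ±0.11) and estimates the general-population
mean at −2.04, next to its true value −2. Because inflated slopes mean
inflated test information, the improper calibration also reports smaller
standard errors for the resulting scores — overstated measurement precision.

The full experiment is one call:

```r
res <- run_study(study_config(master_seed = 42))
person_recovery_table(res)
plot_bias_curves(res)
```

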