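# heatcco

Time-stratified case-crossover analysis of short-term ambient heat
exposure and low 5-minute Apgar scores, with distributed-lag nonlinear
models (DLNM) and a conditional logistic likelihood.

## Who this is for

Environmental and perinatal epidemiologists estimating acute effects of
daily mean temperature on rare birth outcomes from a registry (births with
date and municipality of delivery) linked to municipality-level daily
climate. The package covers the full pipeline:

* **Exposure construction** — hourly-to-daily means, grid-cell to
  municipality averaging, relative humidity via the Tetens equation,
  population-weighted temperature percentiles, lagged exposure tables.
* **Cohort definition** — the low-risk birth exclusion cascade
  (singleton, in-state, Apgar present, 2500–4000 g, 37–41 weeks, no
  anomaly, cephalic; boundaries retained) with conserving accounting, and
  uncorrected Pearson chi-square descriptives.
* **Design** — bi-directional time-stratified referents: control days are
  the other same-weekday days of the case's month and year (3–4 per
  case).
* **Model** — a crossbasis `W[i,(j,k)] = Σ_l B_j(x_il) C_k(l)` combining
  a natural cubic spline in temperature (one internal knot by default)
  with a linear lag term over lags 0–1, humidity adjusted by a 3-df
  spline, fitted by Newton–Raphson on the conditional logistic
  likelihood `Σ_s [z_case'β − log Σ_d exp(z_d'β)]`; odds ratios contrast
  the population-weighted 95th/5th percentile against the 50th, cumulative
  and per lag. Conditional quasi-Poisson on aggregated counts, subgroup
  refits and the published sensitivity variants are included.
* **Synthetic data** — a seeded generator of linked climate + registry
  data with a known injected lag-response, so everything above is testable
  end to end with ground truth.

## Worked example

Simulate a three-year, ten-municipality study of ~300,000 births with a
known cumulative log odds ratio of 0.2 for the 95th-vs-50th percentile
contrast, then run the full pipeline:

```r
library(heatcco)

cfg <- sim_config(seed = 42)   # defaults: ~300k births, injected log-OR 0.2
report <- run_primary(run_config(simulation = cfg))

report$thresholds
#> Population-weighted temperature percentiles (state-wide, n = 10960 municipality-days)
#>    p5   p50   p95
#> 12.95 21.63 30.12

report$outcomes$low_apgar$estimates[, c("contrast", "or", "ci_low", "ci_high")]
#>          contrast    or ci_low ci_high
#> 1 high_cumulative 1.296  1.104   1.522
#> 2       high_lag0 1.157  0.958   1.397
#> 3       high_lag1 1.120  0.927   1.354
#> 4  low_cumulative 0.746  0.609   0.914
#> 5        low_lag0 0.755  0.599   0.952
#> 6        low_lag1 0.988  0.783   1.247
```

Reading the output: the thresholds are the population-weighted 5th, 50th
and 95th percentiles of daily mean temperature (°C) over the simulated
study period. `high_cumulative` is the odds ratio of a low Apgar score
for delivery-window exposure at the 95th vs the 50th percentile summed
over lags 0–1 — here 1.30 (95% CI 1.10–1.52), consistent with the
injected truth exp(0.2) ≈ 1.22 given a standard error of ~0.08 on the log
scale; `high_lag0` / `high_lag1` are the same contrast's single-lag
contributions, whose logs sum exactly to the cumulative log-OR. The
`low_*` rows contrast the 5th percentile against the 50th (protective
here because the injected response is increasing in temperature). The
report also carries the per-subcategory blocks (6–7, 3–5, 0–2), the
exclusion flowchart, and the daily case-rate series.

Sensitivity variants and subgroup refits:

```r
sens <- run_sensitivity(run_config(simulation = cfg),
                        c("no_humidity", "conditional_quasipoisson"))
```

Lower-level building blocks (`tetens_rh()`, `weighted_quantile()`,
`referent_days()`, `expand_cases()`, `build_crossbasis()`, `cco_fit()`,
`predict_or()`) are exported and documented individually; `cco_dlnm()` is
the one-call model front-end with `print`, `summary`, `coef`, `vcov`,
`predict` and `plot` methods. A thin command-line wrapper lives at
`inst/cli/heatcco.R` (subcommands `simulate | exposure | cohort | fit |
report`).

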