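---
title: "Methods: case-crossover distributed-lag analysis of ambient heat and low Apgar scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-crossover distributed-lag analysis of ambient heat and low Apgar scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcco)
```

## The scientific problem

Acute exposure to high ambient temperature around the time of labour and
delivery is hypothesised to impair a newborn's immediate condition through
maternal dehydration, reduced utero-placental perfusion, heat stress and
prolonged labour. The outcome studied here is a *low 5-minute Apgar score*
(a score of 7 or below on the 0–10 vitality index; subcategories 0–2, 3–5
and 6–7), a rare event (~1.1% of low-risk births). Because the outcome is
rare and the exposure is a short-term environmental fluctuation, the
natural design is a **bi-directional time-stratified case-crossover**: each
case serves as its own control, and exposure on the delivery day is
compared with exposure on the other days of the same calendar month that
share its day of week. This conditioning removes, by design, all fixed or
slowly varying individual-level confounding, seasonality, long-term trends
and day-of-week effects; only factors varying day-to-day *within* a
month/weekday stratum — such as weather — can drive the contrast.

`heatcco` implements the complete pipeline: exposure construction from
gridded climate inputs, the low-risk cohort exclusion cascade,
time-stratified expansion, distributed-lag nonlinear modelling (DLNM) with
a conditional logistic likelihood, subgroup and sensitivity refits, and a
seeded synthetic data generator so that every stage is testable without
access to a birth registry or climate reanalysis.

## Exposure model

Municipality-level daily mean temperature is the arithmetic mean of hourly
2-metre air temperatures over a date (requiring, by default, all 24 hours)
and over the grid cells belonging to the municipality (unweighted mean;
cell membership is an input, no polygon geometry is computed). Relative
humidity comes from the Tetens saturation vapour pressure formula,

$$\mathrm{RH} = 100\,\frac{e_s(T_d)}{e_s(T)},\qquad
  e_s(x) \propto \exp\!\left(\frac{17.27\,x}{x + 237.3}\right),$$

with the multiplicative constant cancelling in the ratio. The constants
$a = 17.27$, $b = 237.3\,^\circ$C are the common Tetens calibration;
dewpoints above the air temperature are clamped to saturation with a
warning. Daily RH is the mean of hourly RH values (RH first, averaging
second), because $e_s$ is convex and the two orders of operation differ.

Reference temperatures are **population-weighted percentiles** of daily
mean temperature: every (municipality, day) value enters the pool weighted
by its municipality's population. The weighted quantile uses midpoint
plotting positions $p_i = (\mathrm{cum}_i - w_i/2)/\sum w$ with linear
interpolation — the convention is documented because no single standard
exists; with equal weights it reduces to the ordinary midpoint-rule
(type 5) sample quantile. The analysis contrasts the 95th ("high") and 5th
("low") percentiles against the 50th ("moderate").

## Cohort definition

The exclusion cascade restricts to *low-risk* births: singleton, in-state,
5-minute Apgar score present, birthweight 2500–4000 g, 37–41 completed
weeks, no congenital anomaly, cephalic presentation, and no missing data
on those fields. Boundary values are retained (the inequalities are
strict). Counts are sequential — a record failing two criteria is counted
at the first it fails — so the accounting always conserves:
initial − Σ excluded = final. Percentages are expressed against the
initial total, rounded half-up to two decimals. Descriptive
outcome-by-characteristic tables use the uncorrected Pearson chi-square
(no Yates continuity correction, also for 2×2 tables) with listwise
exclusion of missing categories.

## The model

For case $i$ with lagged exposures $x_{i,l}$ ($l = 0, \dots, L$; default
$L = 1$, the delivery day and the day before), the crossbasis is the
tensor design

$$W_{i,(j,k)} = \sum_{l=0}^{L} B_j(x_{i,l})\, C_k(l),$$

where $B$ is a natural cubic spline basis over temperature (default: one
internal knot; cubic between knots, linear beyond the boundary knots) and
$C$ is the lag basis — by default an intercept plus a linear term in lag,
so the 2-df lag structure over lags 0–1 is unconstrained. The primary
crossbasis therefore has $2 \times 2 = 4$ columns. Lag-window mean RH is
adjusted for with a 3-df natural cubic spline (two internal knots at the
33.3rd/66.7th percentiles of stratum-level mean RH) appended to the
design; it is an adjustment term and never enters effect contrasts.

The conditional logistic likelihood for stratum $s$ (one case day, its
3–4 referent days) is the stratum softmax

$$\ell(\beta) = \sum_s \left[ z_{s,\mathrm{case}}'\beta -
  \log \sum_{d \in s} \exp(z_{s,d}'\beta) \right],$$

maximised by Newton–Raphson with step-halving (convergence when the
maximum absolute score falls below $10^{-8}$ or the relative
log-likelihood change below $10^{-10}$; at most 50 iterations — the
designs are small and well conditioned). Columns constant within every
stratum are unidentifiable and are dropped with a warning. The covariance
is the inverse observed information. Effects are reported as odds ratios
for coefficient-space contrasts

$$a_{(j,k)} = \left[B_j(x_t) - B_j(x_r)\right] \sum_{l \in \mathcal{L}} C_k(l),$$

cumulative ($\mathcal{L} = \{0,\dots,L\}$) or lag-specific; on the log
scale the cumulative effect equals the sum of the lag-specific effects
exactly, and the zero contrast gives OR = 1 exactly. Intervals are normal
delta-method 95% intervals ($\pm 1.96\,\mathrm{se}$, matching the
reporting convention of this literature).

### Knot placement

Knot number and position are, in principle, selected by AIC;
`aic_knot_scan()` reproduces that procedure (AIC $= -2\ell + 2k$, ties
toward the lowest percentile, non-converged candidates excluded). The
default fit places the single internal knot at the median of the
case-crossover exposure values with boundary knots at the observed
extremes, which makes runs deterministic without a scan. A calibration
worth recording: single-knot natural splines whose knots sit at adjacent
percentiles of a concentrated exposure distribution are *nearly
indistinguishable* by AIC — the scan localises a knot reliably only when
the true response has curvature concentrated at the knot and the data are
ample. The package's calibration test therefore uses a peaked spline truth
inside the candidate family, where the scan selects the true knot in a
clear majority of replicates.

### Conditional quasi-Poisson sensitivity

Aggregating daily case counts $y_{sd}$ within the same strata gives the
conditional Poisson (multinomial) likelihood
$\sum_s [\sum_d y_{sd} z_{sd}'\beta - N_s \log \sum_d \exp(z_{sd}'\beta)]$,
an algebraically equivalent estimator when designs depend only on the
municipality-day: the package exploits this equivalence as a cross-check
(agreement within $10^{-6}$). All-zero strata contribute nothing and are
excluded with an accounting. Overdispersion is estimated as Pearson
$X^2$ divided by the residual degrees of freedom; because the fitted
means are stratum-conditional, the residual df counts the conditioned-out
stratum intercepts ($n - S - k$), without which the estimate would be
biased low by construction. A published variant of this model additionally
adjusts for residual autocorrelation at specific lags; that adjustment's
mechanism is not described in enough detail to reproduce and is **not
implemented** here.

Other sensitivity variants respecify the primary model: two internal
temperature knots (at the 33.3rd/66.7th exposure percentiles), no humidity
adjustment, lag 0 only, lags 0–6 with natural cubic splines in both
dimensions (lag knot at the midpoint, lag 3, absent any stated placement),
and a less-restricted sample (all singleton in-state births with an Apgar
score). Subgroup refits hold the global temperature and humidity knots
fixed for comparability, and climate-zone stratification recentres
contrasts on zone-specific percentiles.

## The synthetic data generator

The generator exists so that the whole pipeline — including its failure
modes — is testable with a known ground truth. It emulates:

* **Climate**: per municipality, daily mean temperature = mean level +
  seasonal sinusoid peaking in mid-January (Southern-Hemisphere phase) +
  AR(1) noise; dewpoint = temperature minus a noisy nonnegative
  depression; RH via the same Tetens routine the exposure module uses (so
  RH is physical by construction). An optional hourly mode superimposes a
  zero-mean diurnal sinusoid purely to exercise hourly-to-daily
  aggregation.
* **Births**: Poisson daily counts per municipality; covariates drawn
  from categorical marginals resembling a low-risk cohort; a configurable
  fraction of records violates one low-risk criterion (or has a missing
  Apgar score) so the exclusion cascade and its accounting are exercised.
* **Outcome**: Bernoulli per birth with
  logit $P$ = logit(baseline) + month effect + injected temperature
  effect. The injected effect is *linear in temperature*, split across
  lags by configurable weights and scaled so that the cumulative log odds
  ratio of the 95th-vs-50th percentile contrast equals the configured
  value exactly. A linear response lies inside the span of the natural
  cubic spline, so the configured value is an exact recovery target
  (estimator consistency is tested, not spline approximation error).
  Month effects inject genuine calendar confounding — months are warm
  *and* have elevated baseline risk — which the time-stratified design
  must (and does, in the tests) remove.

Default conditions: 10 municipalities with mean temperatures spread
17–24 °C, three years (2015–2017), ~274 births/day in total (~300,000
births), baseline event rate 1.1%, seasonal amplitude 5.5 °C, AR(1)
$\rho = 0.65$, $\sigma = 2.2$ °C, dewpoint depression 4 °C, cumulative
log-OR 0.2 with lag weights (0.7, 0.3) — same-day exposure dominant —
and month-effect amplitude 0.15 on the log-odds scale. These are one-time
choices of what a realistic mid-sized registry study looks like; the
sample size is set so the injected effect is estimable with a standard
error near 0.08, and seven days of climate history precede the study
window so every lag structure up to 0–6 is computable from the first day.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: heat-induced shifts in labour timing (the
at-risk population is independent of temperature here), gestational-age
dynamics, spatial exposure misclassification within municipalities,
reporting artefacts in registry covariates, and real spatial correlation
between neighbouring municipalities' weather beyond what a shared seasonal
phase induces.

## Numerical choices and degenerate inputs

* Weighted quantiles: midpoint plotting positions, linear interpolation,
  min/max outside the covered range; a single value returns itself for
  every probability.
* Tetens: supersaturated inputs clamped with a warning; inputs at or
  below −237.3 °C rejected.
* Daily means: dates failing the completeness rule become missing, never
  silently partial.
* Lagged exposures: rows with any missing lag are flagged, and
  case-crossover strata containing such a row are dropped whole (complete
  stratum analysis) with a count.
* Newton–Raphson: step-halving on likelihood decreases; coefficients
  exceeding 15 in absolute value flag probable separation; singular
  information aborts the iteration with a non-convergence flag.
* Lag basis for $L = 0$ degenerates to a single intercept column;
  over-parameterised lag splines (df > L + 1) are rejected.
* Zero cases anywhere downstream raise an explicit "no cases" error;
  subgroup levels without cases are reported as absent rather than
  fitted.

## Problem sizes used in the test suite

Unit and property tests run on two-municipality, one-year studies
(~22,000 births, ~450 cases). The calibration checks use the default
configuration: one ~300,000-birth study for point recovery, 200
replicates for interval coverage (93–96% observed for the nominal 95%)
and 200 null replicates for the Kolmogorov–Smirnov check that
$z = \hat\beta/\mathrm{se}$ is standard normal. The AIC-scan calibration
uses 2,500 four-day strata per replicate. These sizes were chosen so the
full suite completes in minutes while leaving each check adequately
powered.

## Known limitations

* The conditional logistic fitter targets the matched-set designs built
  here (one case, 3–4 referents; or aggregated counts); it is not a
  general survival/partial-likelihood engine.
* The quasi-Poisson variant supports exposure-only designs: covariates
  that vary between cases sharing a municipality-day cannot enter the
  aggregated model, matching its role as a rate-denominator check.
* No penalised DLNMs, no temperature–humidity interaction surfaces, no
  alternative referent schemes beyond the time-stratified one.
* Real registry and reanalysis magnitudes (e.g., a published cumulative
  OR of 1.08 over millions of births) are far outside desk-scale
  reproduction; the package's claims are about correctness of the
  machinery, demonstrated on synthetic data with known truth and on
  published descriptive-table arithmetic.
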