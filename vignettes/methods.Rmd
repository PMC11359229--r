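---
title: "Counterfactual attribution of a lockdown's effect on NO2: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual attribution of a lockdown's effect on NO2: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lockdownNO2)
```

## The problem

Daily urban NO₂ is driven jointly by emissions (traffic, industry, heating)
and by meteorology (dispersion, chemistry). When emissions change abruptly —
here, the COVID-19 lockdown that began in Chinese cities on 23 January
2020 — the naive comparison "this year versus previous years" confounds the
intervention with whatever the weather happened to do. This package
implements and compares the two standard deconfounding strategies at the
city level, and ships a synthetic-data generator whose injected effect is
known exactly, so both estimators can be audited.

## Study windows

The intervention winter (1 Dec 2019 – 30 Apr 2020) is split into the
pre-lockdown (BLP, 1 Dec – 22 Jan), lockdown (DLP, 23 Jan – 18 Mar, 56
days) and post-lockdown (ALP, 19 Mar – 30 Apr) windows; the three preceding
Dec–Apr winters are the reference (training) winters, labelled 2017–2019 by
their April end. `period_scheme()` validates that the three 2020 windows are
disjoint, contiguous and cover the winter; per-city deviations (some cities
reopened later) are expressed by passing different boundaries.

## The business-as-usual model

One random forest per city (`randomForest`, 500 trees, 4 candidate
predictors per split — the values retained after a 5 × 6 grid search that
`tune_model_spec()` reproduces) is trained on the reference winters only and
then predicts the intervention winter from the weather that actually
occurred, yielding the no-lockdown counterfactual. The machine-learning
estimate is the observed minus counterfactual DLP mean; its percent form is
taken relative to the counterfactual mean, i.e. relative to what would have
happened without the intervention.

Seven predictors are used: the season label `year` (emission-factor drift),
`day_julian` (within-winter seasonality), `day_lunar` (days relative to the
first day of the Chinese Lunar New Year holiday, the proxy for
holiday-driven emission swings), and wind speed, wind direction, temperature
and relative humidity. The feature table also carries a `weekday` column
(Monday = 1); it is not in the default predictor set — the reference
importance accounting treats the weekly cycle as a 7-variable model — but
`model_spec(predictors = c(default_predictors, "weekday"))` adds it.
Variable importance is node-purity importance normalized to shares summing
to 100 %.

Missing-data policy: rows with any missing predictor or response are flagged
in the feature table, dropped from fitting and skipped in prediction — no
imputation, so every dropped day is visible in the counts. Model fitting
requires at least 100 complete training rows (configurable); each estimator
requires 70 % coverage of its window (configurable), and refuses to report
otherwise, naming the offending period.

The `day_lunar` anchor for 2017 is 27 January; defaults for 2018–2020
(16 Feb, 5 Feb, 25 Jan) follow the official holiday start and are
config-overridable, because "first day of the holiday" versus "New Year's
day" differ by one day and users may prefer either convention. December
dates reference the upcoming winter's holiday, so each Dec–Apr window
contains exactly one `day_lunar = 0`.

## The difference-to-difference estimator

With C̄ the period means, C_d,X = C̄_2020,X − C̄_2017–2019,X for each window
and the adjusted lockdown difference is C_d,DLP − C_d,BLP. Two conventions
needed fixing:

* **Historical pooling.** Days are averaged within each reference winter
  first, then the three winters with equal weight, so a winter with more
  missing days is not down-weighted.
* **Alignment.** The 2020 windows are mapped to identical month–day windows
  in each reference winter (29 February dropped for non-leap winters).
  Holiday-relative alignment would be the natural alternative; calendar
  alignment is the default because it is the convention of
  historical-difference studies, and the misalignment it causes around the
  movable holiday is precisely one of the biases the comparison stage is
  meant to expose.

## Evaluation metrics

The suite is Willmott's original (quadratic) index of agreement
d = 1 − Σ(P−O)² / Σ(|P−Ō|+|O−Ō|)², plus MBE, MAE, RMSE, their
observed-mean-normalized percentages (NMBE, NME, NRMSE) and the squared
Pearson correlation. NME and NMAE are the same quantity here (equal-length
sums) and only the NME label is reported. The index of agreement, not R²,
is the headline skill score: an anti-correlated predictor attains R² = 1
while its index of agreement collapses — the suite's tests pin this case.
Degenerate inputs are explicit: constant observations are unscoreable by d
unless the prediction is identical (then 1, by continuity); normalized
metrics refuse a zero observed mean; R² requires 3 pairs and nonzero
variance. The whole suite is verified against a deliberately naive loop
implementation at 10⁻¹² relative tolerance.

## Health impact assessment

RR = exp(βΔc), AF = 1 − exp(−βΔc) and ΔMort = AF × daily deaths × days,
with Δc the magnitude of the DLP reduction (cities with no estimated
reduction contribute zero). Default β: 0.009 per µg/m³ (non-accidental,
cardiovascular) and 0.012 (respiratory). **β units caveat:** these are
applied per 1 µg/m³, since the risk model applies β directly to Δc;
coefficients quoted per 10 µg/m³ must be divided by 10 before overriding.
Baseline mortality (daily deaths, or rate × population) is user-supplied —
the package bundles no real demographics — so burden outputs are only as
good as those inputs; the algebra is tested (both AF forms agree to 10⁻¹²,
ΔMort is exactly linear in deaths and days), not any specific national
total.

## The synthetic generator

`generate_city()` builds each day's concentration as

> base + trend·(season − 2017) + weekday offset + seasonal harmonic −
> holiday dip · exp(−½ (day_lunar / halfwidth)²) + met terms + noise,

truncated at zero, with the configured lockdown step subtracted on DLP days
of the final winter. Meteorology is seasonal sinusoids plus AR(1) noise
(lag-1 coefficient 0.7, chain restarted each winter), so reference winters
genuinely differ from the intervention winter — without that variability
the two estimators would coincide and their comparison would be vacuous.
The wind-speed term is inverse, c/(1 + ws), mimicking dispersion and making
wind speed the dominant importance variable, as observed in deweathering
practice.

Defaults are fixed once as the emulated study conditions: base level
45 µg/m³ (so the default 16 µg/m³ effect is a ≈ 40 % reduction, mid-range
for the studied cities), year trend −1 µg/m³/yr (slow air-quality
improvement), weekday offsets summing to zero with a weekend dip, holiday
dip 12 µg/m³ with 10-day half-width, daily noise sd 5 µg/m³ (≈ 10 %
normalized error, the order reported for business-as-usual NO₂ models), 2 %
missingness. `dlp_wind_anomaly` multiplies DLP-2020 wind speed to emulate
the stagnant-dispersion anomaly of early 2020; it biases the
difference-to-difference estimator (which cannot see weather) but not the
counterfactual model, and the acceptance tests assert exactly this
direction of failure. The RNG is structured so that two runs differing only
in the injected effect share identical weather and noise, giving an exact
paired-run oracle.

What the generator does **not** emulate: atmospheric chemistry (NOx–O₃
titration), spatial correlation between cities, station-level layouts, and
heavy-tailed pollution episodes. Passing tests therefore demonstrate that
the estimators are correct under the stated statistical structure, not that
any particular real-world number is right.

## Identifiability and its limits

Three measured limitations shape the tests rather than being hidden by
them:

* **Year extrapolation.** The forest cannot extrapolate the ordinal season
  label, so a year trend of τ µg/m³/yr biases the counterfactual by ≈ |τ|.
  The exact-recovery checks therefore use a trendless configuration; the
  stochastic cohort checks keep the default trend and absorb the ≈ 1 µg/m³
  it costs inside their 2 µg/m³ tolerance.
* **Holiday-dip smoothing.** The sharp holiday depression moves across the
  calendar between winters; tree averaging blurs it, costing up to about
  1 µg/m³ of recovery accuracy. Tests assert ≤ 0.5 µg/m³ recovery on the
  smooth calendar-only process and a graded ≤ 1.5 µg/m³ bound with the dip
  restored — alongside the observation that calendar-aligned differencing
  is hurt *more* by the movable holiday than the model is.
* **Truncation at zero.** Never active on the default noiseless structural
  mean (asserted), but with noise and large injected effects occasional
  floor hits slightly shrink observed means; this is realistic (real
  concentrations cannot go negative) and kept.

Problem sizes: unit tests run forests of ~120 trees; the cohort recovery
check runs the full 500-tree specification over two 31-city cohorts, and
the leave-one-winter-out protocol (three folds, training on two winters,
scoring the third with the full metric suite) at the same specification.

## Orchestration and reproducibility

`simulate_cohort()` writes canonical per-city CSVs plus a truth table;
`run_pipeline()` executes features → fit → pre-lockdown validation →
counterfactual prediction → both estimators → cohort comparison → optional
health burden, failing with the city's label on any stage error, and
persists all tables when given an output directory. `table2_summary()`
summarizes any per-city estimate table in the published layout (header-
driven, column order free). All randomness descends from explicit seeds:
per-city seeds are `master_seed + city index`, and a fixed seed makes
simulation byte-identical and fit/predict bit-reproducible on one machine.
A YAML file (`read_run_config()`) carries the periods, holiday calendar,
model settings, coverage threshold and global seed, so a full run is one
config plus one function call.
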