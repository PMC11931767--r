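# microconc

Measuring whether urban point events — in the motivating application,
fatal and nonfatal shooting incidents — remain spatially concentrated at
*microplaces*: individual street segments and intersections. The "law of
crime concentration" holds that a small set of microplaces hosts most
events year after year; `microconc` provides a tested, reproducible
pipeline for asking whether that concentration is rising, stable, or
eroding over a study period, for epidemiologists and crime-analysis
researchers working with event-level case series.

## The statistic and the model

Every event is assigned to exactly one microplace. An event is a **repeat**
if at least one *other* event in the dataset — earlier or later — occurred
at the same microplace; events at single-event locations are non-repeats.
**Spatial concentration** in a given year is the share of that year's
events that are repeats, with repeat status always judged against the full
series (a case-only design: only events can be repeats, so no external
controls are needed).

The time trend is a Bernoulli GLM with a log link (log-binomial
regression):

    P(repeat_i = 1) = exp(β₀ + β₁ · year_i)

so `RR = exp(β₁)` is the **relative risk per year** — the multiplicative
annual change in concentration (RR = 0.982 ⇔ a 1.8 % annual decline).
When the log-binomial likelihood fails to converge the model is refit as a
Poisson working model with robust (HC0 sandwich) standard errors. A
**Monte Carlo permutation null** reshuffles the date–location pairs,
recomputes the repeat indicator, and refits the model; the empirical
p-value is the share of trials whose |log RR| is at least as extreme as
observed.

Because real police incident data are generally restricted, the package
includes a synthetic generator: a jittered-grid street network and a
hot-set allocation process (a small fraction of microplaces receives an
elevated, geometrically decaying routing weight) whose defaults are
calibrated to the published Boston 2007–2021 case series.

## Worked example

```r
library(microconc)

cfg   <- config_boston_2007_2021(seed = 1)     # calibrated preset
net   <- generate_network(cfg)                 # 31,152 microplaces
cases <- compute_repeat_indicators(generate_case_series(net, cfg))

summary_table(cases, net)
#>   group       item                     n   prop   pct
#> 1 microplaces total                31152 NA      NA
#> 2 microplaces intersections        12081  0.388  38.8
#> 3 microplaces segments             19071  0.612  61.2
#> 4 events      total                 3362 NA      NA
#> 5 events      repeat locations      1759  0.523  52.3
#> 6 events      non-repeat locations  1603  0.477  47.7

fit <- fit_log_linear_trend(cases)
fit
#> <trend_fit> log-linear (log-binomial) repeat-probability trend
#>   RR per year: 0.982  (95% CI 0.974, 0.990)  p = 6.68e-06
#>   family: log_binomial  converged: TRUE  cases: 3362 over 15 years

derive_quantities(fit, span_years = 14, mean_annual_events = nrow(cases) / 14.75)
#>   annual_pct_change aggregate_relative_reduction absolute_pp_reduction events_shifted
#> 1             -1.79                         22.4                  13.0           29.6

monte_carlo_null(cases, n_trials = 1000, seed = 2)
#> <permutation_result> Monte Carlo null for the concentration trend
#>   observed log RR: -0.0181  (RR 0.982)
#>   0/1000 trials as extreme; empirical p < 0.001 (permute null)
```

Reading the output: concentration falls by about 1.8 % per year
(RR 0.982); compounded over the 14-year span that is a 22 % relative
reduction, about 13 percentage points in absolute terms, equivalent to
shifting ~30 events per average year from repeat to non-repeat locations.
None of 1,000 reshuffled datasets produced a trend of equal magnitude, so
the decline is not an artifact of the repeat indicator's construction or
of declining annual counts.

`run_pipeline()` wraps the same steps — assignment, concentration, trend,
permutation — around file inputs and writes `summary.csv`, `annual.csv`,
`model.json`, three figures, and a run log. `tidy()`, `glance()`, and
`autoplot()`/`plot_*()` methods are provided for the fitted objects, and
networks/events round-trip through GeoJSON, WKT-CSV, and CSV.

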