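---
title: "Measuring spatial concentration at microplaces: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial concentration at microplaces: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`microconc` quantifies the spatial concentration of event-level case
series — shootings in the motivating application — at *microplaces*,
the street segments and intersections of a city. This vignette is the
package's account of the statistical machinery: the repeat-location
statistic, the trend model, the permutation null, the synthetic data
generator, and the numerical decisions behind each.

## The repeat-location statistic

The unit of analysis is the event, not the place (a case-only design:
only events can be "repeats", so there is no natural control series).
After each event is assigned to exactly one microplace, every event gets
a binary indicator:

* `is_repeat = 1` if at least one *other* event in the dataset — before
  or after it in time — occurred at the same microplace;
* `is_repeat = 0` if its microplace hosts no other event.

The indicator is symmetric at the microplace level: all events at a
microplace with ≥ 2 events are repeats, all events at single-event
microplaces are not. Annual *concentration* is the share of a year's
events that are repeats, with repeat status always evaluated against the
**full** series. This matters: a microplace with one event in the first
year and one in the last contributes a repeat event to both years. The
statistic answers a resource-allocation question — if prevention effort
is directed at places with a history of events, what fraction of events
occur at such places?

```{r, message = FALSE}
library(microconc)
cases <- tibble::tibble(
  event_id = c("a", "b", "c", "d"),
  date = as.Date(c("2007-05-01", "2021-05-01", "2007-06-01", "2010-01-01")),
  microplace_id = c("x", "x", "y", "z")
)
annual_concentration(compute_repeat_indicators(cases))
```

## The trend model

The probability of being a repeat is modeled log-linearly in study year:

$$\Pr(\text{repeat}_i = 1) = \exp(\beta_0 + \beta_1\,\mathrm{year}_i),$$

a Bernoulli GLM with a log link ("log-binomial" regression). The log
link — rather than the logistic — is chosen because its exponentiated
slope $e^{\beta_1}$ is a **relative risk** per year, the directly
interpretable multiplicative annual change in concentration; a logit
link would yield odds ratios, which overstate effects when the outcome
is common (here, around half of events are repeats). Confidence
intervals and p-values are Wald-type on the log-RR scale.

Two numerical points:

* **Year coding.** By default year enters as the integer calendar year,
  centered at the first study year, since concentration is an annual
  summary. A `"fractional"` option codes each event as
  `year + (day-of-year − 1)/365.25` for users who prefer a continuous
  clock; on simulated data the two agree well within one standard error.
  Centering keeps the intercept interpretable as the fitted first-year
  concentration, which the derived quantities reuse as the default
  baseline.
* **Convergence fallback.** The log-binomial likelihood is not globally
  well behaved: fitted probabilities can hit the $p \le 1$ boundary and
  `glm` may fail or diverge. When the covariate is the (discrete)
  integer year, the fit aggregates to per-year binomial totals — the
  identical maximum-likelihood problem with the identical observed
  information, at a fraction of the cost. If the log-binomial fit still
  fails, the model is refit as a Poisson working model with robust (HC0
  sandwich) standard errors, a standard consistent estimator of the
  relative risk for binary outcomes; `family_used` in the returned
  object records which path produced the estimates. Degenerate inputs
  (a single study year, or all outcomes identical) are refused with
  named errors rather than fit.

Derived summaries translate the RR onto the scales practitioners quote:
annual percent change $100(\mathrm{RR} - 1)$; the aggregate relative
reduction over a span of $s$ years, $100(1 - \mathrm{RR}^s)$; the
absolute percentage-point reduction, which multiplies that by a baseline
concentration; and an events-shifted count, which multiplies the
absolute reduction by a mean annual event count. The span and the
mean-annual-events divisor are explicit arguments: for a study running
January 2007 through September 2021 the package's convention is a
14-year span (last full calendar-year increment) and a divisor of
total events / 14.75 elapsed years.

## The permutation null

Could a declining trend in the repeat indicator be an artifact of the
study design — declining annual counts, the finite window, the indicator's
construction — rather than of a changing spatial process? The Monte
Carlo null answers by **reshuffling date–location pairs**: each trial
permutes the observed microplace labels across events (dates fixed),
recomputes the repeat indicator, and refits the trend model with
identical settings. Permuting the *observed* labels, rather than drawing
locations uniformly from the network, is the default because it
preserves the pooled repeat proportion exactly — only the association
between location and time is destroyed — so null trials are directly
comparable to the observed fit. (Uniform redraws are available as
`null_mode = "uniform"` for sensitivity; they collapse the pooled repeat
rate to the much lower uniform-allocation level and test a different,
stricter hypothesis.)

Extremity is two-sided on $|\log \mathrm{RR}|$. With $k$ of $N$ valid
trials at least as extreme as the observed statistic, the empirical
p-value is $k/N$, reported as the bound $1/N$ when $k = 0$ (one cannot
resolve probabilities below the Monte Carlo resolution); the add-one
estimator $(k+1)/(N+1)$ is also returned for users who want a
never-zero version. Trials whose refit fails are recorded as missing and
excluded from the denominator, and more than 50 % failures aborts the
run. Each trial draws from a child RNG stream derived from the root seed
and the trial index, so the null distribution is reproducible
trial-by-trial and independent of execution order.

## The synthetic generator

Real police incident data are restricted, so the package ships a
generator with two layers.

**Network.** A $k \times k$ planar grid with 100-unit spacing and
uniform ±15-unit jitter on node positions; row streets ("S3 St") and
column avenues ("A5 Ave") give every segment a block label and every
intersection a cross-street label, so the label-matching assignment
rules are exercised naturally. Exactly the requested number of segments
(lattice edges, fixed enumeration order) and intersections (grid nodes,
preferring those incident to ≥ 2 generated segments) are emitted.

**Events.** Per calendar year, a Poisson draw around the configured
expected count, dates uniform within the part of the year inside the
study window (a fractional end year like 2021.75 truncates dates and
scales the expected count proportionally). Each event's microplace is
drawn with probability proportional to a routing weight: a fixed random
subset of microplaces (fraction `hot_fraction`) carries weight
`hot_weight0 · weight_decay^(year − first_year)`, everyone else weight
1. This hot-set mechanism is the simplest process that yields both a
high repeat baseline and a smooth, near-log-linear decline as the hot
weight decays toward uniformity; with `hot_weight0 = 1` it degenerates
to uniform allocation, where the per-event repeat probability has the
closed birthday-problem form $1 - (1 - 1/M)^{n-1}$ — the generator's
analytic sanity check.

Randomness is organized as one root seed with deterministic child
streams per stage (layout, hot set, each year, each permutation trial),
so changing one year's expected count cannot perturb another year's
draws, and identical configurations are byte-identical on disk.

**The calibrated preset.** `config_boston_2007_2021()` fixes the study
conditions the package treats as its reference scenario: 19,071 segments
and 12,081 intersections; expected annual counts declining linearly from
309 (2007) to 156 (2019) with a spike of 220 in 2020 and a 2021
full-year rate of 132 truncated at September (expected total ≈ 3,341
events over 14.75 years); and `hot_fraction = 0.01`,
`hot_weight0 = 123`, `weight_decay = 0.961`. The last three were chosen
once, by matching a closed-form approximation of the expected
concentration path (hot/cold repeat probabilities from the Poisson
thinning of events over the network) so that a count-weighted log-linear
fit of that path returns RR ≈ 0.982 per year with a first-year
concentration ≈ 57.6 %. Matching the fitted trend was preferred over
pinning the raw final-year value, because single-year concentrations at
~100 events carry sampling errors of several percentage points; under
the preset the expected final-year concentration is about 44–45 %.

**What the generator does not emulate.** Real street topology (no
dead-end tangles, bridges, or variable block lengths); geocoding noise
and address ambiguity; covariates (neighborhood, demographics, fatal vs
nonfatal); within-year seasonality; and any spatial correlation between
hot places (the hot set is a uniform random subset, not a contiguous
"crescent" of neighborhoods). Passing tests therefore show the
pipeline's statistics are computed correctly and recover known
generative parameters — not that any particular city behaves like the
preset.

## Assignment rules and geometry

Raw locations resolve in a fixed precedence: a cross-street pair beats
an address reference beats coordinates beats a pre-assigned id. Labels
are normalized (lowercase, punctuation stripped, whitespace collapsed)
and cross-street pairs match unordered. Coordinates snap to the
microplace minimizing planar point-to-polyline distance, with ties (to
1e-9 units) broken by the lexicographically smallest id so assignment is
deterministic; a configurable snap threshold (default 100 units, one
grid block) bounds how far a point may be from the network. Events that
cannot be resolved — no location fields, unmatched labels, unknown ids,
or out-of-range coordinates — are never guessed at: they land in an
exclusion log with a reason, and `|assigned| + |excluded|` always equals
the input size. Coordinates are assumed already projected to a planar
CRS; the package deliberately performs no geodetic transformation.

## Verification scale

The test suite verifies the repeat indicator against an $O(n^2)$
pairwise oracle (50 random series up to 500 events), nearest-microplace
assignment against an exhaustive distance scan, parameter recovery of a
generative RR of 0.982 across 200 replicates of 15 years × 10,000
cases (mean bias within Monte Carlo error, ~95 % CI coverage), and
type-I calibration of the permutation test over 200 stationary datasets
× 199 trials. These sizes were chosen so the whole suite runs in a few
minutes while leaving binomial-error bands tight enough to detect real
miscalibration.

## Limitations

* The log-binomial model assumes a single exponential trend; it will
  average over genuine non-monotonicity (an interim peak year, say)
  rather than flag it. Inspect `annual_concentration()` alongside the
  fit.
* The permutation null preserves each event's date exactly and permutes
  at the individual-case level; alternatives that shuffle only across
  years, or within spatial strata, test subtly different hypotheses and
  are out of scope.
* The binary repeat indicator is one operationalization of
  concentration; Gini- or share-based measures (e.g. "5 % of places host
  x % of events") are deliberate non-goals here.
* Empirical p-values are bounded below by Monte Carlo resolution
  ($1/N$); claims below that resolution require more trials, not a
  smaller number.
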