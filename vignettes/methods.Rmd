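---
title: "Methods: valuing farm-dam renovation for cattle weight gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valuing farm-dam renovation for cattle weight gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damcba)
```

## The appraisal problem

Unfenced farm dams in the grazing country of NSW and northern Victoria are
commonly contaminated by direct stock access. Renovation — a 400 m fence, a
gravel hardened watering point, and vegetation planted in the inflow area —
improves water quality, and the available grazing trials report that steers
drinking clean rather than dam-contaminated water gain between 0% and 23%
more weight (about 11% on average across the three studies). `damcba` values
that gain against the renovation costs for the average beef farm of each
region, and propagates the substantial uncertainty in the gain through a
Monte Carlo simulation.

All dollar values are real 2019 AUD. The analysis horizon is 50 years (the
life of a well-built renovated dam) and the discount rate 7% per annum real,
the standard rate for Australian public-project appraisal. Both are
parameters (`discount.horizon_years`, `discount.rate`) and every figure in
this vignette is recomputed when they change.

## Cash-flow conventions

Three timing conventions matter; all are fixed in the finance layer:

* Recurring benefits and costs are end-of-year flows starting at year 1;
  construction happens at year 0 and is undiscounted.
* "Every ten years over a 50-year period" includes the horizon year: events
  fall at years 10, 20, 30, 40, 50. This convention is what makes the
  desilting stream for a poor dam worth $2,997 rather than some neighbouring
  value, and it is applied uniformly.
* Streams whose events have different cycle lengths are compared via
  equivalent annual values (EAV). The renovated-dam desilting stream (years
  20, 40, 60) is valued over its own 60-year cycle, converted to an EAV, and
  the EAV difference against the poor-dam stream is re-annuitised over the
  50-year horizon. The same treatment applies to the watering-point
  maintenance mix ($500 each 10 years, $400 each 15 years, common 60-year
  cycle). Truncating these streams at 50 years instead would misstate the
  comparison because the cycles straddle the horizon.

Arithmetic is carried at full double precision; rounding happens only in the
report renderers (`render_table3()` prints $'000, BCRs to one decimal).

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `discount.rate` | 0.07 | /yr, real | Australian public-appraisal standard |
| `discount.horizon_years` | 50 | yr | life of a renovated dam |
| `benefits.weight_gain_fraction` | 0.11 | — | cross-study approximate average; stored as an assumption, not recomputed from the study table |
| `benefits.base_sale_weight_kg` | 400 | kg | feeder steer sold at the top of the 330–400 kg range |
| `benefits.fertiliser_per_100head_year` | 1047 | AUD/yr | avoided fertiliser, converted dairy-herd estimate |
| `desilting.cost_per_event` | 3000 | AUD | desilting a 1,600 m² dam |
| `dams.ha_per_dam` | 40 | ha | one renovated dam per 40 ha of pasture |
| `costs.*` | see fixture | AUD | itemised supplier quotes; component sums are validated against the stated totals |
| `simulation.gain_lower/upper` | 0, 0.23 | — | the study range; `percent_gain_range()` recovers 0 to 0.234 from the observations |
| `simulation.price_sigma` | 0.14 | — | sd of annual log real returns of feeder-steer prices |
| `simulation.price_init_vic` | 3.03 | AUD/kg | mean Victorian price 2015–2019; NSW adds `nsw_price_offset` 0.16 |

Fractional dam counts are retained (the NSW mean farm has 1,490 ha / 40 =
37.25 dams): the analysis prices an average farm, not an integer build plan.

The bogging/drowning and mastitis channels are carried as explicit
zero-valued parameters (`bogging_saving_per_year`, `mastitis_saving_per_year`)
so sensitivity users can switch them on; the default analysis conservatively
excludes them.

Two reconstructions deserve a note. The watering-point maintenance EAV
computes to $52.11 from its stated components while the published analysis
quotes $52.14 — the exact component timing behind the published figure is not
recoverable, and the $0.03 difference is below reporting precision (the
50-year PV agrees within $1). Similarly the Victorian break-even gain
computes to 1.73% against a published 1.8%; back-calculating from the
published rounded present values gives ~1.7%, so we treat the difference as
print rounding. The farm table's footnote also quotes stocking rates (0.74
Victoria, 0.23 NSW) that disagree slightly with its own mean column
(0.75/0.25); the package carries the table column, and stocking rate is a
derived diagnostic, not a model input.

## The deterministic engine

Benefits are level 50-year annuities at constant 2019 prices: weight gain
`g·w·p·s·A(r,n)`, fertiliser `(herd/100)·1047·A(r,n)`, and the per-dam
desilting saving times the dam count. Costs are the per-dam schedule times
the dam count, capital at year 0. BCR is PV(benefits)/PV(costs) and the
break-even gain has the closed form

```
g* = (PV_costs − PV_fertiliser − PV_desilt) / (w · p · s · A(r, n))
```

because benefits are affine in `g`; the tests cross-check it against a
`uniroot()` solve of the NPV and verify that plugging `g*` back balances the
ledger to under a dollar. If the non-gain benefits alone cover costs, the
break-even is reported as 0 with a message.

```{r deterministic}
run_deterministic("NSW")
100 * break_even_gain("Victoria")
```

## The uncertainty model

Each of 100,000 hypothetical farms draws:

1. a persistent weight-gain fraction `g ~ Uniform(0, 0.23)` — permanent
   idiosyncratic differences between farms, not year-to-year noise (a
   redrawn-per-year variant would average out and understate NPV dispersion);
2. one of the four survey years 2015–2018, equally likely, taken **jointly**:
   cattle sold, herd size and area all come from the drawn year, preserving
   their correlation;
3. a 50-year Victorian price path `P_t = P_{t-1}·exp(r_t)` with
   `r_t ~ N(0, 0.14²)` from $3.03; the NSW path is the Victorian path plus
   $0.16 (perfectly correlated by construction, matching the near-perfect
   observed correlation). Zero-mean *log* returns keep the median path flat
   at the initial price, which is what anchors the simulated median NPV near
   the deterministic value.

The simulated price of year `t` multiplies that year's weight-gain benefit
before discounting; fertiliser and desilting savings and the per-dam costs
stay at their deterministic constructions, with costs varying only through
the sampled area. The offset is added to the price level after
exponentiation; at these magnitudes the alternative (offsetting before the
random walk) differs only in second order.

One RNG stream drives a run, consumed in a fixed documented order — all gain
draws, then all scenario draws, then the return matrix — so a seeded run is
bit-reproducible and the draws are independent of how the arithmetic is
vectorised.

```{r simulation}
run_simulation("NSW", simulation_config(n_replicates = 2e4, seed = 1))
```

### What reproduces and what does not

At 100,000 replicates the simulation reproduces the published NPV and BCR
quartiles for both regions within Monte Carlo tolerance, and the NSW
exceedance probability (~71.5% vs published 70.9%). The Victorian
probability, however, computes to ~92.5% against a published 90.8%. This is
not sampling noise: conditional on a year scenario the probability is
essentially the uniform tail `P(g > g*)`, and averaging the four Victorian
break-evens (1.45%, 1.96%, 1.86%, 1.60%) gives 92.5% analytically, with
price noise contributing under 0.1 points. No variant of the stated model we
examined (return drift, independent column sampling, larger volatility,
offset ordering) yields 90.8% without simultaneously breaking the NSW
quartiles that do reproduce. We therefore report the model's own value and
flag the published figure as resting on an implementation detail the text
does not state.

## Synthetic data

The volatility input (0.14) was estimated from a 2003–2019 price series that
is not public, so the package treats it as a fixture and ships generators
that emulate the missing raw data:

* `generate_price_history()` produces seeded random-walk price series;
  `estimate_log_return_sd()` recovers the volatility (sample n−1 sd of log
  first differences by default; the n denominator is an option since
  published estimates rarely state the convention). The round trip recovers
  a true sigma of 0.14 within 5% on series of 1,000+ years; on 16 returns the
  estimator is unbiased apart from the ~1.6% small-sample sd bias.
* `generate_farm_population()` scatters the survey-year averages with
  multiplicative lognormal noise: a farm-level size factor shared by herd,
  area and sales (80% of the log variance) keeps stocking rates realistic,
  an idiosyncratic remainder keeps the columns from being proportional, and
  mean-1 noise makes population means converge to the survey averages. The
  default dispersion of 0.2 is a test setting, not an estimate of real
  farm-size spread.

These generators emulate the *statistical structure* the model assumes —
lognormal multiplicative noise, year-scenario mixtures — not real price
dynamics (no trends, step-changes or mean reversion) and not the true
farm-size distribution (the underlying survey excludes herds under ~100
head). Tests passing on synthetic data therefore validate the pipeline's
arithmetic and statistical behaviour, not the external validity of the
assumptions.

## Problem sizes and numerical choices

The full 100,000-replicate simulation runs in seconds; the test suite uses
it for the headline reproduction and smaller sizes (500–20,000 replicates)
where only distributional behaviour is being checked, with tolerances set
from binomial/quantile standard errors at three sigma. Quantiles use R's
default type-7 definition. Degenerate inputs are defined rather than
accidental: zero discount rate falls back to the `n`-year limit of the
annuity factor, degenerate gain bounds return the point value, a zero-sigma
path is constant, and a zero-cost farm raises an explicit BCR-undefined
error.

## Limitations

The economics inherits the evidence base's weaknesses: three small North
American trials stand in for Australian conditions, the fertiliser saving
has no attached confidence level, and the uniform gain distribution is an
assumption of ignorance across the study range. The model prices an average
farm — it does not capture farm-level heterogeneity beyond the four survey
years, optimise dam placement, or value biodiversity, greenhouse or
mental-health externalities, and the restocker business model is out of
scope.
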