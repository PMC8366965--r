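# damcba

Cost-benefit analysis of renovating farm dams to improve livestock drinking
water quality on beef cattle farms in south-eastern Australia.

Many farm dams in the NSW/Victorian grassy box-gum woodlands are unfenced and
suffused with dung and urine. Renovating a dam — fencing it off, building a
gravel hardened watering point, and planting filtering vegetation — improves
water quality, and North American grazing trials suggest steers drinking clean
water gain up to 23% more weight. `damcba` asks whether the renovation pays:
it values the extra liveweight sold, the avoided fertiliser, and the reduced
desilting frequency against the per-dam capital and maintenance costs, in
real 2019 dollars over a 50-year horizon at a 7% real social discount rate.

The package is for agricultural and resource economists who want to reproduce,
stress-test or re-parameterise the analysis: every input (the weight-gain
observations, the per-farm survey averages, prices and the cost schedule) is
shipped as an editable fixture, and every published headline number is
recomputed by code.

## The model

Per farm, with annuity factor `A(r, n) = (1 - (1+r)^-n) / r`:

- **Weight-gain benefit** `PV_gain = g · w · p · s · A(0.07, 50)` — additional
  gain fraction `g` (deterministically 0.11), base feeder-steer sale weight
  `w = 400` kg, liveweight price `p` ($3.19/kg NSW, $3.03/kg Victoria), and
  `s` cattle sold per year.
- **Fertiliser saving** `(herd/100) · $1,047 · A(0.07, 50)`.
- **Desilting saving** — a poor dam is desilted ($3,000) every 10 years, a
  renovated dam only at years 20, 40, 60; the two streams are compared via
  equivalent annual values over their own cycles and the difference valued as
  a 50-year annuity (≈ $1,987/dam).
- **Costs** — one dam per 40 ha; per dam: $5,475 fence, $3,048 hardened
  watering point, $374.30 vegetation, plus maintenance PVs ($349.60 fence;
  ≈ $720 watering point from a 60-year mixed 10/15-year cycle).

NPV = PV(benefits) − PV(costs); BCR = PV(benefits)/PV(costs). The break-even
gain solves `PV(benefits)(g) = PV(costs)` in closed form. The Monte Carlo
module simulates 100,000 hypothetical farms: `g ~ Uniform(0, 0.23)` persistent
per farm, prices following `P_t = P_{t-1} · exp(r_t)`, `r_t ~ N(0, 0.14²)`
from $3.03 (NSW = Victoria + $0.16), and the four survey years 2015–2018
sampled jointly and equally likely.

## Worked example

```r
library(damcba)
run_deterministic("NSW")
#> <cba_breakdown> NSW mean farm (PV, $'000 2019 AUD)
#>   Benefits
#>     Value of additional weight gain                 420
#>     Fertiliser saving                                50
#>     Saving due to reduced desilting frequency        74
#>     Total benefits                                  544
#>   Costs
#>     Construction of dam fence                       204
#>     Construction of hardened watering point         114
#>     Planting vegetation                              14
#>     Dam fence maintenance                            13
#>     Hardened watering point maintenance              27
#>     Total costs                                     371
#>   Net Present Value                                 173
#>   Benefit Cost Ratio                                1.5
```

The mean NSW farm (217 cattle sold/yr, 37.25 dams) gains ~$544k of benefits
against ~$371k of costs: renovation pays 1.5:1, and the Victorian mean farm
(denser stocking, far fewer dams per head) pays 3.0:1. Break-even additional
weight gain:

```r
100 * break_even_gain("NSW")      # 6.47  (% per annum)
100 * break_even_gain("Victoria") # 1.73
```

Uncertainty analysis:

```r
run_simulation("NSW", simulation_config(n_replicates = 1e5, seed = 1))
#> <simulation_summary> NSW, 100,000 replicates (seed 1)
#>   NPV ($'000):  25%=-30  50%=185  75%=445
#>   BCR:          25%=0.92  50%=1.51  75%=2.21
#>   P(benefits > costs): 71.5%
```

So even with weight gain uncertain across its whole 0–23% study range and
volatile prices, ~71% of simulated NSW farms (and ~92% of Victorian farms)
come out ahead.

A command-line wrapper is installed at `inst/cli/damcba`
(subcommands `deterministic`, `simulate`, `breakeven`, `fixtures`).

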