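---
title: "A cost-consequence model for workplace wellbeing interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cost-consequence model for workplace wellbeing interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellcost)
```

## The model

`wellcost` implements a deterministic cost-consequence model that an
employer can use to weigh a workplace mental-wellbeing intervention
against current practice ("no intervention"). Poor mental wellbeing
imposes costs on employers through three channels: **absenteeism**
(employees absent through sickness), **presenteeism** (employees present
but working at reduced capacity) and **staff turnover** (employees
leaving and needing replacement). The model values an intervention's
annual effect on each channel in currency and sets the result against
what the intervention costs.

For a participating headcount $N$, per-person intervention price
$c_{\mathrm{int}}$, organisation-level lump sum $C_{\mathrm{fix}}$,
daily unit costs $c_{\mathrm{abs}}$ and $c_{\mathrm{pres}}$, per-case
turnover cost $c_{\mathrm{turn}}$, and annual effects
$\Delta_{\mathrm{abs}}$, $\Delta_{\mathrm{pres}}$ (days avoided per
participant) and $\Delta_{\mathrm{turn}}$ (percentage points of the
participating headcount), the incremental costs are

$$
\begin{aligned}
K_{\mathrm{abs}} &= -N \,\Delta_{\mathrm{abs}}\, c_{\mathrm{abs}}, &
K_{\mathrm{pres}} &= -N \,\Delta_{\mathrm{pres}}\, c_{\mathrm{pres}}, \\
K_{\mathrm{turn}} &= -N \,\frac{\Delta_{\mathrm{turn}}}{100}\, c_{\mathrm{turn}}, &
K_{\mathrm{int}} &= N c_{\mathrm{int}} + C_{\mathrm{fix}},
\end{aligned}
$$

with total incremental cost $K = \sum K_j$ and net cost per person
$K / N$. **Savings appear as negative incremental costs.** This sign
convention is worth stating prominently because intuition often expects
positive "savings": a total of −£5,215 means the intervention saves
£5,215 over the year.

Assumptions the model inherits from this structure:

* **One-year horizon, no discounting.** Effectiveness evidence for
  wellbeing interventions rarely extends beyond 18 months, so costs and
  benefits are annual and undiscounted, in a single currency.
* **Attribution.** Any modelled reduction in absenteeism, presenteeism
  or turnover is attributed entirely to the intervention.
* **Human-capital costing.** Daily unit costs value a lost (or
  lost-equivalent) day at the full cost of a working day — wage plus
  on-costs such as employer national insurance and pension
  contributions. Friction-cost and multiplier approaches, multi-year
  horizons, wellbeing/QALY valuation and societal-perspective costs are
  out of scope.
* **Linearity.** The total is affine in every scalar input; there are
  no capacity constraints, interactions or diminishing returns.

## Inputs and their semantics

| Input | Units | Notes |
|---|---|---|
| `n_participants` | persons (≥ 1) | the *participating* headcount, not company size |
| `cost_per_person` | currency/participant/year | ≥ 0 |
| `fixed_cost` | currency/year | lump sum, does not scale with headcount; ≥ 0 |
| `absenteeism_per_day` | currency/day | ≥ 0 |
| `presenteeism_per_day` | currency/day | ≥ 0; typically above the absenteeism rate, because the inverse association between earnings and sickness-absence rates does not carry over to presenteeism |
| `turnover_per_case` | currency/case | ≥ 0 |
| `absenteeism_days_avoided` | days/participant/year | any sign; negative = worsening |
| `presenteeism_days_avoided` | days/participant/year | any sign |
| `turnover_reduction_pp` | percentage points/year | of the participating headcount: cases avoided = `n_participants * pp / 100` |

Three semantic choices deserve emphasis, because each is forced by how
results must come out in practice:

* **Per-person denominator.** Net cost per person divides by the
  participating headcount. In an opt-in programme where 75 of a
  250-person company take part, a £345 total is £5 per participant
  (345/75), not £1 per employee on the books.
* **Omission versus zero.** A channel without an effect entry is *not
  modelled* and is omitted from results; an effect of exactly 0 is
  modelled and reported as a £0 row. Totals agree either way, but the
  report distinguishes "no evidence" from "no effect". An effect
  without its matching unit cost is a validation error — it cannot be
  monetised.
* **Split intervention cost.** Some interventions are priced per head,
  others funded as a lump sum (for example, a programme fee plus the
  value of working time released across the workforce). Both parts
  coexist; only the per-person part scales in sensitivity analysis on
  headcount.

All arithmetic is carried at full double precision. Rounding happens
only in the report layer (`render_results()`), half away from zero to
whole currency units — the convention that matches how such results are
tabulated (4.6 → 5, −130.375 → −130, −22,099.5 → −22,100). The
"Total costs" row rounds the exact total; it is never the sum of the
rounded component rows, which can differ by a unit.

```{r example}
fx <- bundled_scenarios()
render_results(lapply(fx[c("scenario_3", "scenario_4")], evaluate_scenario))
```

## Sensitivity and break-even analysis

One-way deterministic sensitivity analysis (`one_way()`) substitutes a
single input by its lower and upper bound and re-evaluates the model;
`tornado()` does this for a set of parameters and orders the entries by
descending span for a tornado diagram (`plot()` draws one). Because the
model has no empirical input distributions, the default ranges are
symmetric ±50% bands around each base value (`default_dsa_ranges()`),
a scale-free default that can be overridden per parameter, either in
code or through a config file's `dsa_ranges` section. Ties in span are
broken by the fixed `cc_parameters` order so that output is
byte-stable across runs.

`break_even()` exploits the affine structure directly: for input $p$
with coefficient $b = \partial K / \partial p$ (written out in closed
form per parameter), the threshold is $p^* = p_0 - K_0 / b$, where the
total switches between cost-incurring and cost-saving. Solving
analytically rather than by search keeps the result exact and fast; a
bisection search on the evaluated model serves as an independent
cross-check in the test suite, where the two routes agree to within
$10^{-6}$ relative tolerance across 1,000 randomly generated scenarios.
Two degenerate cases raise a no-threshold error rather than a number: a
zero coefficient (for example, varying a unit cost whose effect size is
zero), and headcount in a scenario with no fixed cost, where the total
scales proportionally and never crosses zero. Headcount is treated as
continuous here — a break-even of 37.4 participants is decision-relevant
even though fractional heads cannot be hired — and a returned threshold
may lie outside the admissible input domain (for example, a negative
price), which signals that no attainable value of that input breaks
even.

```{r breakeven}
break_even(fx$base_case, "cost_per_person")
```

## Price-year adjustment

Published unit costs are usually stated in the prices of their source
year and must be restated before entering the model. `inflate()`
multiplies an amount by the ratio of consumer-price-index values
(annual averages; no monthly interpolation) between two years:
`amount * index[to] / index[from]`. The index series is user-supplied
as a two-column year/index file (`read_price_index()`), because index
values are revised over time and any bundled vintage would go stale;
the series shipped at `extdata/cpih_synthetic.csv` is a synthetic
stand-in for testing and examples only. The bundled case-study unit
costs are stored directly in 2024 prices rather than derived by
uplift, since the source-year convention behind them is not specified.

## Configuration files

`read_scenarios()` reads YAML (or JSON, by file extension) with a
top-level `scenarios` list and an optional `dsa_ranges` list. Parsing
is deliberately strict: unknown keys are rejected with an error naming
them. The intended users include non-programmers editing configs by
hand, and a silently ignored misspelling (`absenteesim_per_day`) would
otherwise produce a confidently wrong result. Validation failures name
the scenario and field. `write_scenarios()` emits the same schema, so
write-then-read is an identity.

## The bundled case studies

Six fixtures (`bundled_scenarios()`) span the model's behaviour space:
a 50-person base case; a 600-person company with lump-sum funding; an
opt-in programme reaching 75 of 250 employees; a turnover-only benefit;
and a micro company where absenteeism worsens by 0.3 days while
presenteeism improves. They are stored as an ordinary config file and
loaded through the strict reader, so the fixtures exercise the same
path as user data.

One documented irregularity: the published presentation of the base
case prints a presenteeism incremental cost of −£174,575, which does
not follow from its own inputs under the model's arithmetic
(50 × 9.6 × £379.51 = £182,164.80), and consequently its printed total
(−£210,373) and per-person figure (−£4,207) differ from what the
formulas give (−£217,963.20; −£4,359.26). This package reproduces the
arithmetic and documents the discrepancy rather than "correcting"
either side; the base-case absenteeism cell (−£40,798), which does
follow from the inputs, is checked exactly.

## What the tests do and do not show

Property tests run the model over randomly generated scenarios: 1–1,000
participants, per-person prices up to £700, fixed costs up to £120,000,
daily unit costs up to £500–£600, turnover cases up to £30,000, and
effects spanning negative (worsening) to strongly positive values, with
each channel present independently. This family probes the arithmetic
(additivity, affinity, sign symmetry, break-even correctness) well
beyond the six fixtures. It does not emulate real data: inputs are
drawn independently and uniformly, whereas real unit costs and effects
are correlated with sector, salary structure and intervention type, and
real effect estimates carry sampling uncertainty the deterministic
model does not represent. Passing tests therefore certify the model's
mechanics, not the realism of any particular scenario — which is
exactly the division of labour intended: the scenario inputs are the
user's evidence, the arithmetic is the package's responsibility.

Problem sizes used by the suite — 1,000 scenarios for the break-even
oracle comparison, 60 for the algebraic properties, 100 inflation round
trips — keep the whole suite under half a minute while making the
probability of an undetected sign or coefficient error negligible, and
every run is reproducible under its fixed seed.

## Known limitations

* Effects are point estimates; there is no probabilistic sensitivity
  analysis and no way to express input uncertainty beyond one-way
  ranges.
* One year, one currency, no discounting; benefits that accrue beyond
  the first year are invisible.
* Wellbeing outcomes that resist monetisation (and wider societal
  benefits to the healthcare system or local authorities) are outside
  the model, so its net costs are conservative for interventions with
  genuine wellbeing benefits.
* The linear structure cannot represent saturation: doubling an effect
  size doubles the saving indefinitely.
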