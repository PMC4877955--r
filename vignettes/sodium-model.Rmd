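---
title: "A Markov cohort model of dietary sodium reduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of dietary sodium reduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltsim)
```

## The model

`saltsim` simulates the remaining lifetime of a closed adult cohort — the
2011 New Zealand population aged 35 and over, about 2.3 million people —
under dietary sodium reduction policies. The cohort is stratified by sex,
ethnicity (Māori / non-Māori) and thirteen five-year age bands (35–39 …
95–99), and moves through annual Markov cycles across seven states:

* `healthy` — no cardiovascular disease;
* `chd_year1`, `chd_later` — first and subsequent years with coronary
  heart disease;
* `stroke_year1`, `stroke_later` — likewise for stroke;
* `dead_cvd`, `dead_other` — death from CVD case fatality or from any
  other cause.

The first-year disease states are tunnel states: they exist because the
first year of CHD or stroke carries a much higher health-system cost than
subsequent years, and survivors move deterministically into the `*_later`
state after one cycle. The four conceptual health states of the underlying
model — healthy, CHD, stroke, dead — are recovered by collapsing the
tunnels and the two death causes.

Each five-year stratum is expanded into single-year-of-age sub-cohorts
(260 in all) that age one year per cycle, with rates looked up from the
band containing the attained age. Simulation runs from the 2011 baseline
until every sub-cohort has died or reached age 100; survivors of the
age-99 cycle are absorbed into other-cause death, and nothing accrues
beyond age 100.

### Transition structure

Annual transition rates per stratum are CHD and stroke incidence (from
`healthy`), disease-specific case fatality (from the disease states to
`dead_cvd`), and background non-CVD mortality (from every alive state to
`dead_other`). Within a cycle, competing risks are resolved jointly by the
exponential formula: with rates $r_1, \dots, r_k$ the total exit
probability is $1 - e^{-\sum r_i}$, apportioned among causes in proportion
to their rates. This keeps every row of the transition matrix stochastic
for any non-negative rates, which a naive per-cause $1 - e^{-r_i}$
conversion does not guarantee. The model has no CHD↔stroke transitions and
no joint-disease state: a healthy person acquires at most one disease, a
deliberate simplification consistent with the four-state description.

Baseline occupancy seeds prevalent CHD and stroke cases into the
subsequent-year states (prevalence is dominated by non-incident cases) and
the remainder into `healthy`.

### Secular trends

Incidence and case fatality for both diseases decline at 2.0 % per year,
and background mortality at 1.75 % (non-Māori) and 2.25 % (Māori) per
year, from 2011 to 2026; all rates are held constant thereafter. The
`trended_rate()` helper implements
$r(y) = r_{2011}\,(1+\mathrm{apc})^{\min(y-2011,\,15)}$. No trend is
applied to morbidity weights or blood pressure.

## The sodium → blood pressure → risk pathway

An intervention removes a fraction $f$ of daily sodium intake at full
implementation, phased in over $k$ equal annual steps beginning in 2011
(step $j$ applies for the whole of calendar year $2010 + j$). The
average-adult fraction is rescaled to each sex by its baseline intake
(4013 mg/day men, 3115 mg/day women, average adult 3544 mg/day), so the
sex-specific reduction in year $y$ is

$$\Delta\mathrm{Na}(y) = f \cdot \mathrm{intake}_{\mathrm{sex}} \cdot
\min\!\bigl(1, (y - 2010)/k\bigr) \quad \text{mg/day}.$$

Converted to mmol/day (23.0 mg per mmol), the reduction lowers systolic
blood pressure by an age-specific amount per 100 mmol/day — 5.5 mmHg under
age 40, 6.6 in the 40s, 9.2 in the 50s and 10.3 at 60–69 — linear in dose.
The response table ends at 60–69; we carry the 10.3 value forward to all
older ages. This is a conservative reading of an open question: the
published table simply stops, and reusing the last value neither
extrapolates the rising trend nor discards the effect.

A systolic reduction of $\Delta$ mmHg multiplies disease incidence by
$\mathrm{HR}^{\Delta/20}$, the log-linear dose–response implied by
meta-analytic hazard ratios per 20 mmHg. Published values give only ranges
across ages — 0.49–0.67 for CHD, 0.38–0.67 for stroke, attenuating with
age. Per-band point estimates are interpolated log-linearly in band start
age between the most protective value (anchored at bands up to age 40) and
the least protective (anchored at 85+), which keeps every value inside the
printed interval and reproduces the known age attenuation. The exact
per-decade values the original analysts used are not published; the
interpolation is this package's own choice and is validity-checked against
the printed ranges.

Multipliers apply to incidence from the healthy state only — the stated
causal chain links blood pressure to event probability, not to prognosis
after an event — and the do-nothing comparator has multipliers of exactly 1.

### Built-in interventions

| scenario | reduction (average adult) | phase-in | one-off cost |
|---|---|---|---|
| `subst59` | 51.5 % | 5 years | NZ$3.68 m |
| `subst25` | 21.8 % | 5 years | NZ$3.68 m |
| `bread280` | 7.9 % | 5 years | NZ$3.68 m |
| `bread400` | 2.3 % | baseline year | NZ$3.68 m |
| `do_nothing` | 0 | — | 0 |

The bread fractions come from share arithmetic exposed as
`bread_share_shift()`: a legal concentration maximum rescales bread's
20.6 % share of dietary sodium by the post-law/baseline concentration
ratio (270/439 or 390/439), and the share lost is the intake reduction.
The printed substitution fractions (51.5 %, 21.8 %) are taken as
authoritative inputs rather than recomputed from source shares, which
would give 51.3 % for the larger intervention; the table's figures win.
The sex rescaling is applied uniformly to all four interventions — the
source does not say whether bread-derived reductions were rescaled
differently, and uniformity is the simpler reading. The one-off law cost
is charged once, undiscounted, in the baseline year (where the discount
factor is 1 anyway).

## Economics

QALYs weight each alive state by a utility: $1 - \mathrm{pYLD}$ for
healthy time, additionally minus the disability weight (0.081 CHD, 0.226
stroke) in disease states, where pYLD is the stratum's prevalent-YLD
background morbidity decrement. Costs use a sex × age-band schedule:
healthy annual cost, and first-year / subsequent-year costs per disease,
anchored for a 60-year-old woman at NZ$2381 (healthy), NZ$16,258 / 5,395
(CHD) and NZ$20,553 / 5,991 (stroke) in 2011 dollars. All state costs are
scaled by 1.2 (the inverse 83 % public share of health spending) and by
1.1 / 1.2 / 1.3 at ages 65–74 / 75–84 / 85+ for unfunded residential care.
The healthy-state cost is already net of the CVD-attributable component,
so disease costs do not double-count; end-of-life costs are folded into
the state costs rather than modelled separately (the source notes their
inclusion but gives no separate parameter).

Accrual is full-year on end-of-cycle occupancy with no half-cycle
correction — the validation target is an annual-cycle macro-simulation
that uses none — and discounting is $(1+r)^{-(y-2011)}$ at 3 % by default
(0 % and 6 % as scenario analyses). Incremental results against the
do-nothing comparator are classified *dominant* (more QALYs, lower cost),
*dominated*, or reported as an ICER when both deltas are positive.
Per-adult group results divide a group's deltas (plus its
population-proportional share of the one-off cost) by its 2011 population.

## The synthetic-input generator

The administrative rate and cost surfaces the original analysis consumed
are not public. `generate_inputs()` emulates their statistical structure
so the full pipeline is runnable and testable:

* **Rate surfaces** are Gompertz-like — log-rate linear in age — with
  multiplicative differentials (Māori 1.8× CHD and 1.7× stroke incidence,
  1.6× background mortality; male 1.5× CHD, 1.2× stroke, 1.4× background
  mortality). Levels are plausible magnitudes for a developed-country 35+
  population (e.g. CHD incidence 5 × 10⁻⁴/yr at 45 for non-Māori women,
  doubling roughly every 8 years). A seeded log-normal perturbation
  (SD 0.05) makes surfaces seed-dependent; monotone-in-age and
  Māori ≥ non-Māori orderings are re-enforced after perturbation.
* **Anchors** — the cost schedule values at the female 60–64 cell, sodium
  intakes, disability weights — are reproduced exactly for every seed.
* **Population** is a deterministic 2011-like pyramid totalling 2.3
  million, split by a declining-with-age Māori share (12 % at 35) and a
  rising female share.
* **Prevalence** is incidence × a nominal duration (8 years CHD, 6
  stroke), capped at 0.4.

The generator reproduces the qualitative structure the published results
depend on — age-increasing rates, higher Māori and male burdens, costs
concentrated in the first disease year — but **not** the actual New
Zealand point estimates. Passing tests therefore demonstrate correct
mechanics and correct directionality (scenario ranking, dominance, equity
gradients, age/time distribution of gains), not numeric agreement with the
published lifetime totals, which are unattainable without the restricted
administrative tables.

## Uncertainty analysis

`run_psa()` re-runs the comparator and every scenario per Monte Carlo
iteration under a sampled parameter overlay:

* intervention sodium reduction: normal, SD = 10 % of the point estimate,
  redrawn if outside $(0,1)$;
* hazard ratios: normal per band × disease, SD = 10 % of the point
  estimate, redrawn if outside $(0,1)$;
* costs: gamma multipliers with mean 1 and SD 0.10, one per cost component
  (each cell is marginally gamma with SD = 10 % of its mean; cells within
  a component move together);
* disability weights: beta, moment-matched to the printed 95 % CIs after
  rescaling those CIs to the central estimates — the printed intervals are
  quoted for one demographic stratum and the stroke average lies at the
  quoted upper bound, so the relative width is the transferable quantity —
  with resampling outside the rescaled bounds rather than clamping (no
  probability mass piles up at the bounds).

All parameters are sampled independently. Draws use one counter-based
substream per (parameter, iteration): each substream seed is a
deterministic hash of the master seed, a parameter label and the iteration
counter, so adding a parameter never perturbs another parameter's draws
and results are bit-reproducible. The central estimate is the
all-point-estimates run; 95 % uncertainty intervals are 2.5th/97.5th
empirical percentiles (type-7 interpolation, cross-checked in the tests
against `stats::quantile`). The default is 2000 iterations; the test suite
uses 5–80 iterations per property, which is ample for collapse,
reproducibility and split-half checks while keeping the default test run
around a minute.

## Numerical choices and degenerate inputs

* Occupancy conservation is maintained to well below 1e−9 at every cycle;
  the engine is validated against a transition-matrix-power oracle at
  1e−12 on constant-rate instances.
* Zero rates, zero doses and zero discount rates are exact identities, not
  limits: a zero-reduction zero-cost scenario yields bitwise-zero
  incremental results.
* Ties in the league table are broken by scenario name for stable output.
* Input files are written with 17 significant digits; the read/write round
  trip is lossless at tolerance 0.
* Validation is total: malformed values produce named violations (table,
  field, stratum) instead of errors.

## Limitations

Beyond the generator's synthetic rate levels, the model inherits the
scope of the analysis it implements: no stomach-cancer or renal pathways,
no potassium/magnesium co-benefits of salt substitution, no recurrence or
severity progression within disease states, no migration, no societal
perspective (productivity), no baseline blood-pressure distribution (the
BP effect enters only through the incidence multiplier), and no
model-structure uncertainty in the PSA. The 95+ age band is treated as
95–99 with a hard stop at 100.
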