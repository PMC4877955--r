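# saltsim

Population-level dietary sodium reduction is among the most attractive
preventive policies for cardiovascular disease, but its value depends on
long-run, whole-population accounting: how many quality-adjusted
life-years (QALYs) a policy buys, what it does to health-system budgets
over the remaining lifetime of today's adults, and who — by sex, ethnicity
and age — receives the gain. `saltsim` is an R implementation of the
Markov macro-simulation used to answer those questions for New Zealand:
a closed cohort of 2.3 million adults aged 35+, stratified by sex,
ethnicity (Māori / non-Māori) and five-year age band, simulated in annual
cycles from 2011 until death or age 100.

It is written for health-economic modellers and epidemiologists who want
a transparent, fully testable version of this class of model — the kind of
audience that uses `heemod`, `hesim` or a multi-state life table.

## The model in brief

States are healthy, first/subsequent-year CHD, first/subsequent-year
stroke, and death (CVD or other cause). Annual transition rates — CHD and
stroke incidence, case fatality, background mortality — are stratum- and
age-specific, decline by secular trend (−2 %/yr for incidence and case
fatality, −1.75 %/−2.25 %/yr for non-Māori/Māori background mortality)
until 2026, and convert to probabilities by the joint exponential
competing-risk formula *p<sub>exit</sub>* = 1 − e<sup>−Σr</sup>,
apportioned in proportion to rates.

An intervention removing a fraction *f* of daily sodium (phased in over
*k* equal annual steps) lowers intake by
Δ*Na* = *f* · intake<sub>sex</sub> · min(1, (*y*−2010)/*k*) mg/day,
lowers systolic blood pressure by an age-specific response (5.5–10.3 mmHg
per 100 mmol/day), and multiplies incidence by HR<sup>ΔsBP/20</sup> with
age-attenuating hazard ratios (0.49–0.67 CHD, 0.38–0.67 stroke per
20 mmHg). QALYs and 2011-NZ$ health-system costs are accrued per cycle,
discounted at 3 %, and compared against a "do nothing" comparator to give
incremental QALYs, net costs and an ICER or dominance classification.
Parameter uncertainty is propagated by Monte Carlo (default 2000
iterations) to 95 % uncertainty intervals.

The national administrative rate/cost tables behind the original analysis
are not public, so the package ships a synthetic-input generator
(`generate_inputs()`) that emulates their structure — Gompertz-like age
curves, Māori and male differentials, exact published cost/sodium/
disability-weight anchors — making the full pipeline runnable and
testable. See the methods vignette (`vignettes/sodium-model.Rmd`) for the
model, the generator's design and its limitations.

## Worked example

```r
library(saltsim)

inputs <- generate_inputs(seed = 1)
inputs
#> Model inputs for a closed-cohort sodium-reduction simulation
#>   strata: 52 (2 sexes x 2 ethnicities x 13 age bands)
#>   population: 2,300,000 persons aged 35+
#>   baseline year: 2011; trends frozen after 2026
#>   sodium baseline: 4013 (men) / 3115 (women) mg/day
#>   generator seed: 1; fingerprint 7d42806551e01b137271dc349d8cfc41

scenario <- builtin_scenarios("subst59")   # 59% salt substitution law
scenario
#> Scenario 'subst59': 51.5% sodium reduction, 5-year phase-in, one-off cost NZ$3,680,000

comparator <- accrue(run_cohort(inputs, builtin_scenarios("do_nothing")), inputs)
result <- incremental(accrue(run_cohort(inputs, scenario), inputs), comparator)
result
#> Incremental result, 'subst59' vs do-nothing
#>   delta QALYs (discounted): 231,370
#>   delta costs (discounted): NZ$-744,819,250
#>   classification: dominant (more QALYs, cost-saving)
```

On these synthetic inputs the substitution law gains about 231,000
discounted QALYs over the cohort's remaining lifetime and *saves* roughly
NZ$0.74 billion — more QALYs at lower cost, so it dominates the
comparator rather than having an ICER. (The published analysis, on the
real administrative surfaces, reports the same classification with larger
totals; the synthetic surfaces reproduce structure, not point estimates.)

Distributional results per adult, and the timing of the gain:

```r
group_results(result, inputs$population)
#>       group population cost_per_adult qalys_per_adult
#> 1   under65    1713542           -309          0.1084
#> 2    65plus     586458           -368          0.0777
#> 3    female    1240250           -247          0.0855
#> 4      male    1059750           -414          0.1182
#> 5     maori     185176           -343          0.1247
#> 6 non_maori    2114824           -322          0.0985

early_window_shares(result, age_cut = 65)   # % of first-decade QALY gain under 65
#> [1] 21.2
```

Per-adult gains are larger for Māori than non-Māori (0.125 vs 0.099
QALYs) and for men than women — the interventions reduce health
inequality because baseline CVD rates are higher in those groups — and
about a fifth of the first decade's gain accrues below age 65.
`run_psa()` adds 95 % uncertainty intervals; `league_table()`,
`decompose_age_time()` and `plot_age_distribution()` produce the ranked
scenario table and the age-at-accrual × decade decomposition. A thin
command-line wrapper (`inst/scripts/saltsim`) exposes
`generate-inputs`, `run`, `psa` and `report` subcommands.

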