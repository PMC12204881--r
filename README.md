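# meicost

Monte Carlo lifetime-cost simulation of three surgical pathways for
treating conductive and mixed hearing loss, from the perspective of a
statutory health insurer:

* **Group 1** — direct implantation of an active middle ear implant
  (Vibrant Soundbridge type), with re-implantations, revisions, audio
  processor upgrades and annual check-ups over the remaining lifetime;
* **Group 2** — one or more hearing-improvement surgeries
  (tympanoplasties) first, then a switch to the implant;
* **Group 3** — hearing-improvement surgeries only.

A single intervention makes the implant look expensive (roughly 14,000 EUR
versus roughly 4,000 EUR for a tympanoplasty), but tympanoplasty success
durations are short and recurrences accumulate costs for decades. The
package simulates whole treatment careers to compare what each pathway
costs over a lifetime, how predictable those costs are, and when switching
to an implant pays off.

## Model

For each simulated patient, the observation period is
`TOP = LEX − AFI` (fixed life expectancy `LEX = 81` minus the drawn age at
first intervention), derived through a bound-correction cascade and clamped
to `[1, LEX − MIA]`. All event times and costs are drawn from published
parametric distributions (shifted Weibull, lognormal, triangular, shifted
exponential; see `?model_parameters`), and every future cost is discounted
at `DIR = 5%` per year:

    PV(c, t) = c / (1 + DIR)^t,   t = round(event time − 0.5)

Lifetime cost is the sum of the pathway's components, e.g. for group 1

    LTC = CFI + CRI + CRE + APU + TSC

(first intervention, re-implantations at the drawn implant lifetimes,
revisions, processor upgrades every `TAP ≥ 6` years, and the annual
check-up annuity). Event counts are capped (2 re-implantations,
3 revisions, 12 upgrades, 6 pre-implant surgeries, 15 surgeries in the
surgeries-only pathway); capability-style rates report how often the caps
are hit (`EP_*`) and how often first failures/revisions occur before a
given year (`DR_*`). Cohorts are summarised with means, medians, the
homogeneity coefficient `mean/(mean + sd)`, Welch and Bonett tests, cost
per successfully treated life-year (a ratio of sums), and an
age-threshold treatment strategy that routes patients by remaining
lifetime. See the vignette in `vignettes/` for the full methodology.

## Worked example

```r
library(meicost)
params <- model_parameters()                    # published input set
g1 <- run_cohort(params, "g1", 10000, seed = 4711)
summarize_costs(g1$ltc)
#>      n    mean      sd  median homogeneity
#>  10000 28345.1 6090.45 28051.5    0.823135
100 * spec_limit_rate(g1$first_fail_year, 10, "lower")
#> implant failures before year 10: 5.69 %
cost_per_successful_year(g1$ltc, g1$successful_years)
#> 1057.52 EUR per successfully treated year

simulate_strategy(params, 10000, seed = 4711)
#> <strategy_result>  n = 10000
#>   lifetime cost: mean 29033.22 EUR (sd 8422.86), median 30433.22
#>   cost per successfully treated year: 1083.19 EUR
#>   arm shares:
#>     g3_age_first            16.08%
#>     g3_age_second            6.02%
#>     g1_direct               23.46%
#>     surgery_then_implant    54.44%
```

The direct-implant cohort costs about 28,300 EUR over an average 26.7-year
horizon with a homogeneity of 0.82 (predictable costs); about 5.7% of
first implants fail within ten years. The age-threshold strategy (surgery
only below 14 remaining years, direct implant above 35, otherwise one
surgery with a conditional switch) costs about 29,000 EUR on average —
above direct implantation but well below always operating first.

A command-line front end is included:

```sh
Rscript inst/cli/meicost.R run --group g1 --n 10000 --seed 4711 --out out/
Rscript inst/cli/meicost.R reproduce --out out/   # reference comparison tables
Rscript inst/cli/meicost.R validate               # internal consistency checks
```

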