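---
title: "Lifetime-cost simulation of middle ear implant treatment pathways: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime-cost simulation of middle ear implant treatment pathways: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meicost)
```

## The decision problem

Conductive and mixed hearing loss that cannot be served by conventional
hearing aids is treated surgically: either by hearing-improvement
surgeries (tympanoplasties, possibly with passive prostheses), which are
comparatively cheap but prone to recurrence, or by an active middle ear
implant, which is expensive up front but durable. A payer deciding which
pathway to reimburse faces very different cost *careers*: a tympanoplasty
patient may need a dozen operations over a long life, while an implant
patient mostly needs processor upgrades and check-ups. `meicost`
simulates these careers as a Monte Carlo model and compares three
pathways: direct implantation (group 1), surgeries then implant
(group 2), and surgeries only (group 3).

The model deliberately prices *time under successful treatment*, not
hearing outcome: within the simulated intervals between interventions,
treatment success is assumed comparable across pathways. Audiometric
results, quality-of-life weights (QALYs) and hearing-aid fitting costs
are out of scope.

## Inputs

All inputs are fixed scalars or fitted parametric distributions
(`model_parameters()`, also shipped as
`inst/extdata/default_parameters.json`). The fitted families were
identified from hospital treatment data of the original study and are
consumed here as published — the package does not refit them.

| Input | Meaning | Default |
|---|---|---|
| `lex` | life expectancy (years) | 81 (fixed) |
| `mia` | minimum implantation age (years) | 5 (fixed) |
| `dir` | annual discount rate | 0.05 (fixed) |
| `foa` | flat-rate outpatient appointment (EUR) | 145 (fixed) |
| `apu` | audio processor price (EUR) | 5719.9 (fixed) |
| `ttua` | minimum processor-upgrade interval (years) | 6 (fixed) |
| `afi` | age at first intervention (years) | Weibull(244.32, 2866.74) − 2806.09 |
| `isb` | implantation cost (EUR) | lognormal(9.57283, 0.07429) |
| `lts` | implant lifetime (years) | triangular(−3, 0, 400) |
| `ttr` | time to revision (years) | triangular(−3, 0, 140) |
| `rev` | revision cost (EUR) | lognormal(8.29047, 0.20121) |
| `ttub` | extra upgrade time (years) | Exp(1.41988) |
| `thit` | time under surgical care before implant (years) | lognormal(0.70939, 1.3453) |
| `dsh` | success duration of one surgery (years) | Weibull(0.68361, 1.74601) + 0.28273 |
| `his` | surgery cost (EUR) | lognormal(8.2339, 0.25662) |

Two conventions matter and are kept verbatim from the source model:

* The triangular event-time distributions have a *negative* lower bound
  (−3 years). Draws are **not** truncated by the sampler; the trajectory
  equations floor them at zero (`if(LTS1 < 0; 0; LTS1)`). The point mass
  at zero that this creates is part of the model.
* The symbols `ISB` and `REV` are drawn **once per run** and reused for
  every re-implantation/revision of that run, because the published
  equations reuse the symbols. A `independent_event_costs` switch is
  reserved for per-event draws but intentionally not implemented. The
  three age draws `AFIa/AFIb/AFIc` are treated as i.i.d. from the single
  published age distribution — the source lists one distribution "for
  lower/upper bound correction" and does not state a coupling.

## Per-run trajectory

**Observation period.** `TOP = round(lex − AFIa)`, with fallbacks to the
second and third age draw when the candidate exceeds the upper check or
drops below one year, a floor at 1, and a final clamp at `lex − mia`
(`compute_top()`). The published cascade uses the literal constant 77 in
its upper check although the final clamp is `lex − mia` = 76; the cascade
is reproduced verbatim, including this asymmetry.

**Rounding and discounting.** All rounding is *half away from zero* (the
spreadsheet convention of the source model), not R's banker's rounding.
An event at cumulative time *t* is charged in integer year
`round(t − 0.5)`, clamped at 0 (`event_year()`): a failure at time 0
would otherwise be discounted at year −1, since `round(−0.5)` is −1 under
this convention. Costs are discounted as `c/(1+dir)^year`; the annual
check-up annuity has the closed form
`foa·((1+dir)^(TOP−1) − 1)/((1+dir)^(TOP−1)·dir)` with the analytic limit
`foa·(TOP−1)` at `dir = 0`.

**Event cascades.** Up to 2 re-implantations (at cumulative implant
lifetimes), 3 revisions and 12 processor upgrades (every
`TAP = round(ttua + TTUb)` years) fit into the horizon; in group 2 the
horizon of the implant phase is `TSB = TOP − THI` and all its discount
exponents are offset by the pre-implant time `THI = min(round(THIt), TOP,
25)`. Surgery phases schedule up to 6 (group 2) or 15 (group 3)
operations by the drawn success durations. One published idiosyncrasy is
kept verbatim: the *first* further-surgery condition compares the
unrounded `DSH1` against the horizon while later conditions compare
rounded cumulative sums, so the count of surgeries (`NHI`, unrounded sums
throughout) can differ from the number of costed surgery terms in
borderline runs. Group 2 also charges the implant unconditionally — even
in runs where `TSB = 0` the implant is bought, discounted at year `TOP`.
A consequence worth knowing: while `TOP` is still inside the pre-implant
phase, one extra year of horizon *discounts the implant further* and can
lower the lifetime cost, so cost monotonicity in `TOP` holds for groups 1
and 3 everywhere but for group 2 only once `TOP` exceeds the drawn
pre-implant time.

**Model-quality outputs.** Each run carries signed error years
(`EP_* = horizon − sum of capped event durations`; positive means the
caps truncated a needed event) and rounded first-failure/first-revision
years. Cohort-level rates are capability-style shares
(`spec_limit_rate()`): share of runs *above* an upper spec limit (0 for
the `EP_*` errors) or *below* a lower one (e.g. first failures before
year 10). The 10-year implant failure share has a closed form under the
triangular lifetime distribution, `1 − 390²/(403·400) ≈ 5.645%`, which
the test suite uses as an analytic oracle.

## Random numbers

One root seed; run *i* uses the *i*-th L'Ecuyer-CMRG substream
(`parallel::nextRNGStream`), and every variate is produced by inverse
transform from that substream's uniforms in a fixed symbol order. Run *i*
is therefore reproducible independently of the cohort size and of any
vectorisation, and a shorter cohort is a strict prefix of a longer one
with the same seed. The caller's RNG state is saved and restored. All
samplers are validated against closed-form moments (4 standard errors at
n = 100,000) and, for the triangular family, against the analytic CDF via
a Kolmogorov–Smirnov distance bound.

## Cohort statistics

* `summarize_costs()`: mean, sample SD (n−1), median, and the homogeneity
  coefficient `mean/(mean+sd)`. The source reports homogeneities without
  a formula; this definition (the German casemix homogeneity coefficient)
  reproduces every reported value, e.g. 28,325/(28,325+6,121) = 0.822.
* `compare_groups()`: Welch's unequal-variance t-test for locations (the
  source says only "t-test"; the cohort variances are demonstrably
  unequal) and Bonett's (2006) test for equality of two standard
  deviations, hand-implemented with the pooled kurtosis about trimmed
  means and the small-sample correction; its type-I error is checked by
  simulation in the test suite.
* `cost_per_successful_year()`: ratio of sums, total cohort cost over
  total successfully treated years — not a mean of per-run ratios. For
  groups 1 and 2 the successful years are the observation period (for
  group 2 reduced by the positive part of the pre-implant model error),
  for group 3 the observation period minus the care gap
  `max(0, EP_NHI_G3)`.
* `conditional_cost_table()`: strata by *exact* equality of an integer
  outcome (`TOP` = 10/20/30; `NHI` = 1..5 with the direct-implant cohort
  as level 0 and level 6 excluded, matching the source's tabulation).
  Empty strata are reported missing, never as zero.

## Cost-curve crossings

`crossing_year()` reports the first sign change of two curves on the
integer duration grid — no sub-year interpolation. Two design choices
here were genuinely open:

* The conditional cost difference between the direct-implant and
  surgeries-only cohorts is only tens of EUR per stratum near the
  crossing, while single-year strata of a 10,000-run cohort carry
  Monte-Carlo errors of several hundred EUR. The acceptance tests
  therefore resolve the crossing on 500,000-run cohorts (a few seconds
  each), where the sign pattern is stable.
* For the cost-per-successful-year comparison the surgeries-only curve is
  stratified by *rounded successfully treated years* rather than by
  nominal horizon: runs whose care collapses early contribute at the
  duration they actually achieved. With this reading the advantage of the
  implant begins around year 14; stratified by nominal horizon it would
  coincide with the mean-cost crossing (16–17), because care gaps are
  rare below 20 years.

## The age-threshold strategy

`simulate_strategy()` routes each run by remaining lifetime: below 14
years, surgery only; above 35, direct implant; in between, one surgery
first, then at the scheduled second intervention a switch to the implant
if the remaining years exceed 13. Two timing conventions needed fixing
because the rule is stated in prose only:

* the *decision* uses the model's scheduling year of the second
  intervention, `event_year(DSH1)` (this reproduces the published arm
  shares);
* the *switched trajectory* is evaluated with the verbatim group-2
  equations with the pre-implant time fixed at `round(DSH1)` — the same
  rounding the group-2 model applies to convert continuous surgical-care
  time to the integer `THI`.

With these conventions the strategy's mean cost, SD, cost per successful
year and arm shares all reproduce the reference values; fixing both to
`event_year(DSH1)` instead underprices the switched arm by about 2%.

## Problem sizes and runtime

The published cohort size is 10,000 runs per group, which the acceptance
tests and the acceptance script use for all headline quantities (a cohort
simulates in well under a second). Property suites use 500–2,000 runs;
the literal-interpreter equivalence oracle runs 1,000 runs per pathway at
a 10⁻⁹ tolerance; the crossing analyses use 500,000-run cohorts as
explained above.

## What the generator does and does not emulate

The sampler reproduces the published input *distributions* exactly, so
passing tests demonstrate that the trajectory arithmetic, capping,
discounting and cohort statistics are faithful to the model — not that
the model matches any particular hospital's reality. Real treatment
histories exhibit features the model abstracts away: correlated event
times within a patient, implant survival improving by device generation,
mortality spread around a fixed life expectancy, and price drift in the
reimbursement catalogues. The model is also deliberately conservative:
its failure and revision rates slightly exceed the observed ones.

## Known limitations

* Discounting is annual and event years are integers; no continuous-time
  discounting.
* Fixed life expectancy (81 years) for every patient; no mortality model.
* One cost draw per run for implantations and revisions (see above).
* The small boundary discrepancy between the analytic one-year rates
  (e.g. 3.49% first-year revisions under the triangular CDF) and the
  reference's printed 3.32% suggests the original implementation used a
  slightly different rounding boundary for these diagnostics; the
  ten-year rates used for validation are insensitive to it.
* Reported p-values below 0.001 are floored as "<0.001"; no
  multiple-testing correction is applied, matching the source tables.
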