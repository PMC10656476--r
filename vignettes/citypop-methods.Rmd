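---
title: "Methods: city-level cohort-component projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: city-level cohort-component projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citypop)
```

This vignette is the package's own account of its model: what is computed,
which assumptions and parameters drive it, where the design was genuinely
open and what we chose, and what the tests do and do not demonstrate.

## The projection model

The state is a non-negative real-valued array of person counts by city, sex
and single year of age, with ages 0–99 plus an absorbing open interval
`100+`. Counts are never rounded during projection: rounding each year
would accumulate bias over ninety annual steps.

One annual step composes four operations, in this order:

1. **Year rates.** City ASFR schedules are rescaled by one national factor
   to the scenario's TFR for the year; city mortality schedules are
   rescaled to the year's life-expectancy targets; migration rates are
   built from the 2010 baseline rates via the scenario multipliers, the
   temporal interpolation, the settlement-policy factors and the ceiling
   check (all against the *previous* year's totals).
2. **Migration balance.** Person-count flows are `population × rate` at
   city and province level; provincial nets are rebalanced to a zero
   national sum and city nets reconciled to their province, separately for
   every (sex, age) slice, because the balance constraints carry age and
   sex subscripts.
3. **Births** from the previous year's women aged 15–49 and the year's
   fertility, split by the year's sex ratio at birth. Newborns are not
   survived, migrated, or scaled by the international factor in their
   birth year: the birth equation carries none of those terms, and we
   follow it literally.
4. **Survival + migration + international factor**, cohort by cohort:
   `(P·(1−q) + N_ad)·(1+g)`, then every cohort ages one year and survivors
   of age 99 and of `100+` pool into `100+`. Pooling is the only
   convention that does not lose centenarians under an `a+1` recursion.

With a single city, no migration and constant rates this is exactly a
Leslie-matrix iteration; the test suite exploits that by comparing a
50-year run against an explicitly constructed 202×202 two-sex Leslie
matrix power (relative tolerance 1e-9).

## Scenario parameters

| parameter | units | default / path | rationale |
|---|---|---|---|
| TFR targets | births/woman | 2050: 0.7, 1.3, 1.5, 1.8, 1.8; 2100: 0.9, 1.3, 1.8, 1.8, 2.1 | scenario grid anchors |
| TFR history | births/woman | 1.5 (2010), 1.50 (2013), 1.88 (2017), 1.30 (2020), piecewise linear | observed; shared by all scenarios — scenarios are about futures |
| SRB | male/female births | linear from baseline (default 1.18) to 1.07 at 2050, then constant | long-term normalization target; the 2010 start is a parameter because only the endpoint is pinned |
| international migration | fraction/yr | −0.3015‰ through 2050, linear to 0 at 2100 | see "open decisions" |
| LE growth | years/decade | `e0_city + (t/10)·e0_city/e0_national` | ratio-attenuated decade rule |
| provincial multipliers (2020) | — | ±50% / ±25% / unchanged | region attractiveness scenarios |
| city tier multipliers (2020) | — | T1 +100/+50/0, NT1 +75/+25/0, T2 +50/0/0, T3 −75/−25/0 (%) | tier attractiveness scenarios |
| migration fade | — | linear 2010→2020 to the multiplied rate, linear 2020→2035 to exactly 0 | migration winds down by 2035 in every scenario |
| settlement reform | — | <3M: ×0.5 pre-2020, ×0.1 after; 3–5M: ×0.5 pre-2020, ×0.25 after | 50%/90% and 50%/75% reductions of migration scale |
| ceilings | persons | per-city input; the shipped register carries Beijing's 23 million | absolute override: rate 0 in any year the previous total is at/above the cap |

## Open design decisions

Several points were genuinely underdetermined; the package picks one
reading, documents it, and keeps it testable:

- **International migration timing.** The narrative description of the
  path ("constant in the second half of the century" yet "zero by 2100")
  is internally contradictory. We hold the rate constant through 2050 and
  decay linearly to the unambiguous 2100 endpoint of zero.
- **TFR → ASFR allocation.** Scenarios prescribe national TFR only. We
  multiply every city's schedule by the single factor
  `target / baseline national TFR`, where the baseline national TFR is
  the female-population-weighted (women 15–49) mean of city TFRs. City
  relative differences and schedule shapes are preserved exactly.
- **LE growth attenuation.** "One year per decade, taking into account
  the initial city/national ratio" is read as growth multiplied by the
  ratio. Cities below the national baseline then gain slightly less than
  a year per decade, so the national person-weighted gain lands at or just
  under one year per decade — consistent with a realized national average
  slightly below the nominal rule.
- **Mortality inversion.** The LE target is turned into a schedule by
  uniform proportional scaling `q' = min(1, k·q)` with `k` solved by
  bisection to 0.01 years. This is the simplest monotone one-parameter
  family; a Brass logit transform would be a documented alternative with
  more shape freedom but a second parameter to pin.
- **"Decrease 50%" for loss provinces** deepens the (negative) rate —
  scenario 1 amplifies 2010 flows by 50% on *both* sides, matching the
  narrative of stronger eastern attractiveness and deeper middle-western
  losses. For Tier-3 cities, by contrast, "decrease" shrinks the rate
  magnitude toward zero (reduced migration scale). Both choices are
  isolated in `region_multiplier()` / `tier_multiplier()`.
- **Proportional cutback** is applied to the surplus side only: the side
  of the provincial balance with the larger magnitude is scaled by
  `min/max`, the smaller side untouched. This is the minimal perturbation
  consistent with cutting back "excess" migration.
- **Sign-mismatch fallback.** When a province's raw city sum and its
  adjusted target disagree in sign (or the sum is zero), multiplicative
  scaling is undefined or explosive; the discrepancy is then distributed
  additively in proportion to each city's previous-year population of the
  same (sex, age). The fallback lives in one function and is exercised by
  hand-built toys.
- **Ceiling re-check.** The cap compares the previous year-end total to
  the ceiling every year, so migration resumes if a city later falls
  below its cap; the policy text speaks only of "that year".
- **Rate timing at the year boundary.** The year-`t` step uses year-`t`
  fertility and mortality with year-`t−1` populations, as the recursion
  equations are written.

## Numerical choices

- Provincial balancing and city reconciliation enforce their constraints
  *exactly*: after proportional scaling, the floating-point residual of
  each (province/sex/age) slice is assigned to the largest-magnitude
  entry. Balancing is idempotent, never flips a provincial sign and never
  increases a provincial magnitude; property tests assert all three on
  seeded random instances, plus agreement with a brute-force
  implementation of the cutback definition on small instances.
- Cohorts driven negative by net outflow are clamped at zero and the
  shortfall is logged per year in the result's `vitals`, preserving an
  audit trail of any mass imbalance. The annual bookkeeping identity
  `total(t+1) = total(t) + births − deaths + international` is asserted
  to 1e-9 relative whenever no clamping fired.
- The life table uses `a_x = 0.5` in closed intervals and `L = l/m` in
  the open interval with `m = q/(1 − q/2)`; degenerate inputs (zero
  mortality everywhere) yield infinite life expectancy, and the engine
  leaves such schedules untouched rather than inverting an undefined
  target. A zero-fertility baseline likewise projects zero births instead
  of attempting to rescale a shapeless schedule.
- Life-expectancy bisection tolerance is 0.01 years; the generator's
  Gompertz calibration uses 0.005 years so that generator error does not
  consume the inversion budget.
- Writers emit 6 significant digits with fixed row ordering, making
  outputs byte-reproducible (hashes are compared in the tests).

## The synthetic study system

Real census microdata are not shipped; the generator builds a baseline
with the statistical structure the model assumes, at a desk scale of
**5 provinces × 4 cities ≈ 20 million people** (the size used throughout
the test suite and by `scripts/acceptance.R`; a 10 × 20 = 200-city system
is used once where a tight Monte-Carlo mean is needed).

- **Mortality**: Gompertz hazards (`β` = 0.095 male / 0.105 female) with
  the level calibrated per city and sex so life expectancy lands near
  72.4 (M) / 77.4 (F) years with ±0.35-year city jitter — a 2010-like
  schedule.
- **Fertility**: a unimodal gamma-shaped ASFR over ages 15–49 peaking in
  the mid-20s, scaled so each city's TFR is within 1% of 1.5.
- **Pyramids**: each city's stable-age distribution under its own rates
  (Lotka growth rate solved from the Euler–Lotka equation), with 2%
  multiplicative noise. Stable initialization avoids artificial cohort
  waves that would obscure model behaviour in tests.
- **Migration**: a young-adult age profile (normal, mode 25); eastern
  provinces positive, middle-western negative, magnitudes around 4‰, the
  loss side rescaled so national person-weighted provincial flows sum to
  ≈ 0 at baseline; city rates vary around their provincial value and can
  flip sign.
- **Seeding**: one master seed with fixed per-component substreams, so
  geography and baseline are individually reproducible regardless of call
  order.
- The **pseudo-census** multiplies each city's projected counts by a
  lognormal factor (default σ = 0.05), giving a truth with known error
  structure: the expected mean city APE is `E|1/f − 1|·100 ≈ 4%`, which
  the validation tests verify by Monte Carlo.

What the synthetic world does *not* emulate: real city-size
distributions, cohort waves from historical shocks (famine, boom years),
age-heaping and census undercount, administrative boundary changes, or
correlation between migration and city size beyond the tier weights.
Passing tests therefore demonstrate the *mechanics* — balance constraints,
conservation, scenario anchoring, error accounting — not forecast skill
for any real country.

## Known limitations

- Net migration only; no origin–destination structure.
- The provincial balance treats the national system as closed apart from
  the single international rate applied uniformly.
- The tier/region register for a real 362-city run must be assembled
  externally; the shipped register covers only the explicitly classified
  T1/NT1/T2 cities and the one published ceiling (Beijing, 23 million).
- Education, urbanization and uncertainty quantification are out of
  scope.
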