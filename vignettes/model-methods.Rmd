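---
title: "Methods: the cohort model, its parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cohort model, its parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaoinvest)
```

## The model in one page

`oaoinvest` implements a deterministic Markov cohort life table for a
closed cohort of children and adolescents aged 0–19 at an index year
(default 2025). Every (age-at-index, sex) stratum advances in annual
cycles until it reaches the maximum age (default 90), so a cohort that
starts at age 0 is followed for 90 years. Within each cycle:

1. **Weight-status distribution.** The stratum's mean BMI comes from a
   linear calendar-time trend fitted to historical series; the BMI
   distribution is Normal with SD proportional to the mean; prevalences of
   normal weight, overweight, and obesity are the tail areas relative to
   the age- and sex-specific cutoffs.
2. **Mortality.** The all-cause annual death probability is background
   (non-modelled) mortality plus the sum over modelled obesity-related
   causes of the baseline cause-specific rate scaled by `1 - PIF`, where
   the potential impact fraction is
   `PIF = (sum(p * RR) - sum(p' * RR)) / sum(p * RR)` for baseline
   prevalences `p`, scenario prevalences `p'`, and relative risks `RR` by
   weight category.
3. **Burden accounting.** Deaths at age `a` contribute `max_age - a`
   years of life lost; years lived with disability accrue as the cause YLD
   rate times person-years lived, also scaled by `1 - PIF`; DALYs are
   their sum. Health outcomes are not discounted (see below).

The *attributable* baseline burden reported in the output tables is the
difference between the baseline run and an all-normal-weight
counterfactual (every stratum's overweight and obese mass moved to normal
weight, PIF applied without an implementation lag). With unit relative
risks this difference is identically zero, which the test suite exploits.

The economic engine converts person-time and YLL streams into five
monetary streams — child and adult excess healthcare costs, wage losses,
productivity losses (absenteeism/presenteeism), and the full-income value
of life-years lost — discounts them to the index year, and computes
`ROI = (B - C) / C` on discounted totals over 10-, 30-, 50-year and
lifetime horizons (horizons count from the index year inclusive).

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `discount_rate` | fraction/year | 0.03 | standard health-economics rate |
| `gdp_multiplier` | — | 1.6 | full-income value of a life-year |
| `gdp_per_capita` | CNY/person-year | 190 000 | metropolitan-level value |
| `exchange_rate` | CNY/USD | 7.1 | used for the paired USD columns |
| `wage` | CNY/worker-year | 120 000 | average annual wage |
| `wage_penalty` | fraction | 0.05 | lifetime wage loss for adults affected in childhood |
| `absenteeism_loss` | fraction | 0.03 | product lost per affected worker-year |
| `bmi_sd_fraction` | — | 0.12 | coefficient of variation of BMI within a stratum |
| `tracking` | fraction | 0.8 | persistence of childhood prevalence reductions into adulthood |
| `lag` | years | 1 | delay between a prevalence change and its health effect |

Adult cutoffs are 25/30 kg/m²; child cutoffs are +1 SD and +2 SD against a
growth-reference table. The packaged reference is synthetic (see below);
users with a real reference supply it to `cutoff_scheme()` in the same
schema.

The five default interventions carry the coverage scale-ups of the
investment case they model — marketing restrictions 0→80 % (ages 2–18),
mandatory front-of-package labelling 5→100 % (all ages), nutrition
counselling 0→40 % of affected children, family-based 0→80 % (ages 6–7),
school-based 5→80 % (ages 6–17) — over a 20-year implementation window,
with a linear ramp that reaches the target in the final window year.
Effect sizes are not published for these interventions; the defaults
(0.10, 0.02, 0.15, 0.10, 0.08 relative prevalence reduction among covered
persons) were chosen once as mid-range values of the school- and
community-intervention effect literature, with clinical counselling of
affected children strongest and a labelling policy weakest. They are
ordinary inputs: override them in `intervention_spec()`, or use
`calibrate_effect()` to solve for the effect that reproduces a reported
lifetime DALY reduction (the mapping from effect to DALYs averted is
continuous and strictly increasing, so the root is unique and found with
`uniroot` to a 1e-10 tolerance).

## What the synthetic generator emulates — and what it does not

`generate_bundle()` produces every input table the pipeline consumes:

* cohort population by single year of age and sex (mean 75 000 per cell,
  ±8 % uniform jitter, roughly a large-metropolis cohort of ~3 million);
* historical mean-BMI series per stratum (25 years ending the year before
  the index year): a linear trend (child slopes ≈ 0.06 kg/m²/year, adult
  ≈ 0.04–0.045, male slightly above female, matching the rapid secular
  BMI rise in urban China) plus Gaussian noise (SD 0.1 kg/m²), which is
  exactly the data-generating process the projection stage assumes;
* six synthetic obesity-related causes with overweight/obese relative
  risks drawn from (1.2, 3.0), obese always at least the overweight RR;
  cause-specific mortality claims an age-increasing share (at most 35 %)
  of a Gompertz-shaped all-cause schedule, so background mortality is
  non-negative by construction; YLD rates follow a logistic age ramp;
* unit costs (child/adult × overweight/obese excess healthcare costs),
  an employment-rate schedule, and the economic scalars.

Because the generator records its ground truth (trend slopes, relative
risks), the test suite can verify *parameter recovery*: with noise SD set
to zero the fitted slopes reproduce the configured slopes to 1e-8, and the
calibration helper recovers a known effect size to 1e-6 from the DALY
reduction it causes.

The generator deliberately does **not** emulate several features of real
surveillance data: cohort effects and non-linear BMI trends (the truth is
exactly linear, so trend-fit bias cannot be detected), correlation between
BMI and mortality inputs, migration in or out of the cohort, secular
trends in treatment and background mortality, and reporting error in
population counts. Green tests therefore demonstrate that the pipeline's
arithmetic and bookkeeping are correct under the model's own assumptions,
not that those assumptions describe any particular city.

## Numerical and design choices

* **YLL reference.** Residual life expectancy to the fixed maximum age
  (90), not a standard life table, so the horizon of a newborn matches the
  model horizon exactly and `DALY = YLL + YLD` holds cell by cell.
* **Cycle convention.** Deaths occur at cycle end: survivors at the start
  of a year accrue a full person-year, and the dead lose whole years. A
  `half_cycle` flag moves deaths to mid-cycle (half a person-year and half
  a YLL less per death) for users who prefer the correction; it is off by
  default to keep the annual bookkeeping exactly enumerable.
* **Background mortality** is the residual of all-cause minus modelled
  causes, floored at zero, so a mis-specified disease table can never
  produce negative background rates.
* **Adult BMI grid.** Mean BMI is updated when a cohort reaches each
  5-year grid age (20, 25, 30, …), evaluated at the calendar year of
  attainment, and held constant in between; linear interpolation between
  grid ages is available via `adult_method = "linear"`.
* **Incremental coverage.** Effects and per-person costs apply to coverage
  *above baseline*: whatever the baseline coverage already achieves is
  embedded in the observed baseline epidemiology, and its cost is sunk.
  The published target coverages are reached in the final window year of
  the linear ramp.
* **Tracking ratchet.** The reduction in force for a stratum is
  `max(active, tracking * cummax(active))`: while interventions are
  active the achieved reduction applies directly; once a cohort ages out,
  the best reduction achieved persists for life attenuated once by the
  tracking coefficient (default 0.8, consistent with the strong tracking
  of weight status from adolescence into adulthood). The ratchet form
  guarantees that adding a weaker intervention can never erase a stronger
  one's tracked benefit, and that benefits are monotone in coverage and
  effect.
* **Combination rule.** Packages combine member reductions as independent
  residual risks, `1 - prod(1 - r_i)` (an `additive_capped` alternative is
  provided, and always dominates it). No super-additive interaction is
  modelled.
* **Costing modes.** Policy interventions (marketing restrictions,
  labelling) are fixed annual programme costs — their budgets cover
  planning, operations and enforcement rather than per-child delivery;
  person-level interventions cost per covered person-year, using
  index-year stratum populations as the exposure base (child mortality
  over the window is small enough that scenario-dependent survivor counts
  would change costs only in the fourth significant digit, and a
  scenario-independent base preserves exact package cost additivity).
* **Discounting.** Money is discounted at `1/(1+r)^t` with `t = 0` in the
  index year; costs are discounted on the same basis as benefits. Health
  outcomes are undiscounted by default (`discount_health` exists as a
  switch but the shipped tables do not use it): burden and DALY tables are
  conventionally reported in natural units.
* **Currency duality.** Every USD figure is its CNY twin divided by the
  exchange rate, exactly; rounding happens only at display time.
* **Determinism.** The generator seeds a local RNG and restores the
  caller's RNG state; a given seed yields a byte-identical written bundle,
  and a given configuration yields identical output checksums, which the
  run manifest records (MD5 per table).

## Problem sizes used in the tests

The test suite runs the full pipeline on bundles with the default cohort
(40 strata, 91 calendar years, 6 causes; about 3 500 cohort-state rows per
scenario), which keeps a complete nine-scenario run under a few seconds.
Engine-vs-enumeration oracle checks use toy cohorts of at most three
strata and two causes, where exhaustive year-by-year enumeration is
practical; the PIF oracle draws 1 000 random prevalence/relative-risk
configurations.

## Known limitations

* Uniform intervention effectiveness across strata: effect sizes do not
  vary by sex, age (beyond eligibility), or socioeconomic position.
* The prevalence-effect mode moves distribution mass but not the mean BMI
  of survivors within a category; a mean-shift effect mode would require a
  distributional model of within-category change.
* YLD is prevalence-rate based (rate × person-years), not an
  incidence-based lifetime accumulation.
* No probabilistic sensitivity analysis: `sensitivity_grid()` is a
  one-way/grid deterministic tool.
* The model excludes wider fiscal effects (tax revenue, food-industry
  GDP) by design, consistent with a societal cost perspective.
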