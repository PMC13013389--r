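---
title: "Methods: the 2023 Nutri-Score dietary index and its mortality pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 2023 Nutri-Score dietary index and its mortality pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscox)
```

This vignette is the package's own account of its science: the scoring
model and its conventions, the dietary index, the survival models, the
synthetic-data generator, and the numerical and design choices made where
the underlying algorithm or standard practice leaves room.

## 1. The food-level score

The 2023 updated Nutri-Score nutrient profiling model assigns each food
or beverage integer points from its composition per 100 g (solid foods)
or 100 mL (beverages). Unfavourable components — energy (kJ), total
sugars (g), saturated fat (g) and salt (g) — earn "A" points; favourable
components — fibre (g), protein (g) and the percentage of fruits,
vegetables and legumes (FVL) — earn "C" points. The score is `A − C`,
higher meaning poorer nutritional quality; for general foods it spans
−17 to +55 and maps onto the letter classes A–E.

Category-specific rules:

* **Beverages** use stricter energy and sugar scales and their own
  protein thresholds; the best class for a scored beverage is B — class
  A is reserved for plain water. Water bypasses the tables entirely and
  carries numeric score 0 where a number is needed (the dietary index).
* **Fats, oils, nuts and seeds** replace absolute saturated fat with the
  saturates-to-total-fat ratio (×100) and use a compressed energy scale;
  their A band extends to −6.
* **Conditional protein rule**: a food whose A total reaches 11 earns no
  protein points unless it holds the full FVL component; cheese is
  exempt; red meat and products thereof are capped at 2 protein points.

All thresholds, point values, letter bands and rule constants live in
`inst/extdata/nutriscore_tables_2023.yaml`. The engine is entirely
table-driven, so a transcription correction never touches logic, and
`score_extrema()` computes each category's attainable range by exhaustive
enumeration of the component point sets (honouring the conditional rule),
not by sampling.

### Numerical conventions

* **Boundary semantics.** A value exactly equal to a threshold earns the
  lower point count ("strictly greater" earns the next band). The one
  exception is the saturates ratio of the fats category, whose printed
  bands ("10 to < 16" …) close on the left; that component is declared
  with a `boundary: ge` attribute in the table file rather than special-
  cased in code.
* **Units at ingestion.** Composition databases report kcal and sometimes
  sodium; Nutri-Score thresholds are kJ- and salt-based. `score_foods()`
  converts once at ingestion (1 kcal = 4.184 kJ; salt = sodium × 2.5).
* **Degenerate inputs.** The ratio rule with zero total fat contributes
  0 points (the limit convention); negative nutrient values and FVL
  above 100% are validation errors naming the field.
* The FVL component's points are not contiguous (0, 1, 2, 5 for foods;
  0, 2, 4, 6 for beverages); the table format therefore stores explicit
  point values, validated to start at 0 and increase strictly.

## 2. From FFQ responses to the dietary index

FFQ responses arrive on the nine-level ordinal frequency scale from
"never or almost never" to "more than six times per day". The published
instrument prints only the endpoints; the interior servings/day constants
are standard FFQ conventions fixed as configuration
(0, 2/30, 1/7, 3/7, 5.5/7, 1, 2.5, 5, 7). Daily intake of an item is
servings/day × portion size, and nutrients follow from the per-100 g
composition. An item absent from a participant's responses counts as
level 1 (zero intake); a wholly missing FFQ at a follow-up visit
contributes no row, so the cumulative average is carried forward
unchanged.

Cohort exclusions are applied in a documented order, each participant
counted under the first reason that applies: (1) missing baseline dietary
data; (2) implausible energy — below 500 or at/above 3500 kcal/day for
women, below 800 or at/above 4000 kcal/day for men, with strict `<` on
the low side and `≥` on the high side; (3) no follow-up.

The dietary index is the energy-weighted mean score of everything
consumed,

$$\mathrm{DI} = \frac{\sum_i NS_i E_i}{\sum_i E_i},$$

a convex combination of the consumed scores. It is computed on raw
intakes: the energy weighting is intrinsic to the definition, while the
residual method (`residual_energy_adjust()`: OLS of the intake on total
energy, residual plus the fitted value at mean energy) applies to
nutrient and food covariates. The exposure carried into the survival
models is the cumulative average of the DI from baseline to each visit,
which damps within-person noise; at baseline it equals the baseline DI,
and the k-th update moves it by at most 1/k of the innovation.

### Quintiles

Cut points are the 20/40/60/80th percentiles of the analysis-wide
distribution of the **final** cumulative-average exposure, computed once
by linear interpolation between order statistics (`quantile(type = 7)`,
reproducible bit-for-bit). The time-varying quintile covariate is the
quintile of the current cumulative average against those fixed cuts;
whether cut points should be recomputed at each annual update is not
settled practice, and fixed cuts keep quintile membership interpretable
across time. Values exactly at a cut point go to the lower quintile.
Per-quintile observed medians feed the trend test.

## 3. The survival models

`build_intervals()` splits each participant's follow-up into half-open
periods `[start, stop)` at their FFQ visit times, exposure updated
exactly at visits with no interpolation, event placed on the final
interval. Person-time is conserved by construction.

* **Quintile models** (`fit_cox`): start–stop Cox partial likelihood with
  quintile indicators (Q1 reference), Efron tie handling (the standard
  choice when tie handling is unstated), and cluster-robust sandwich
  variance over a household cluster identifier. Cause-specific models
  censor competing deaths at the time of death.
* **Trend test**: the per-quintile median exposure enters the same
  adjusted model as a continuous variable; the Wald p of its coefficient
  (robust SE) is the trend p.
* **Per-SD models** (`continuous_sd_model`): the exposure is divided by
  the SD of the baseline exposure distribution of the analysis set.
  Which SD standardises "per 1 SD" is ambiguous in common usage; the
  baseline distribution is chosen because it is well-defined before any
  deaths truncate the series, and the synthetic-data generator
  standardises the same way so recovery experiments compare like with
  like.
* **Interactions** (`interaction_test`): likelihood-ratio test of
  exposure×modifier product terms on plain (non-robust) fits — the LRT
  needs the partial likelihood — with cluster-robust subgroup estimates
  refitted per stratum. Continuous modifiers (age, the Mediterranean
  diet adherence score, ultra-processed food intake) are dichotomised at
  the analysis median.
* **Covariate sets**: the minimal model adjusts for age (years,
  continuous) and sex; the full model adds total energy (kcal/day),
  intervention group (3 levels), education (3), smoking (3), physical
  activity (MET-min/day), BMI as the printed binary at 25 kg/m²,
  alcohol (g/day), family history of cancer, diabetes, hypertension and
  hypercholesterolemia. Complete cases are assumed; analyses are run on
  the post-exclusion cohort.
* **Early-death sensitivity** (`sensitivity_exclude_early`): drops
  participants who died within the first 1 or 2 years (reverse-causality
  guard) and refits with the main-analysis cuts held fixed.
* **Fine–Gray** (`fine_gray`): subdistribution hazards via weighted
  risk-set expansion (`survival::finegray` with the participant id, so
  start–stop exposure updates are supported) followed by a weighted Cox
  fit. Cause-specific and subdistribution models answer different
  questions and are both available, labelled distinctly.
* **Baseline-exposure models** (`baseline_di_models`): the time-fixed
  baseline DI replaces the cumulative average; with a single FFQ the two
  coincide exactly.

## 4. The synthetic-cohort generator

`cohort_config()` bundles every knob. The defaults emulate a multicentre
Mediterranean prevention cohort of older adults at high cardiovascular
risk: ~7,000 participants (men 55–80, women 60–80, ~42% male), a
137-item FFQ repeated annually, staggered administrative censoring
giving a median follow-up near 6 years, an overall death fraction near
6% split across cardiovascular : cancer : other causes in roughly
103 : 169 : 153 proportions, and per-1-SD hazard-ratio truths of 1.38
(CVD), 1.0 (cancer) and 1.10 (other). Generation proceeds in four
seeded stages (food table, covariates, FFQ responses, survival), each
deterministic given the configuration seed.

* **Food table**: category-specific plausible composition ranges, with
  two anchor items (a legume-like profile scoring −17 and an
  energy-dense confectionery profile scoring +55) pinning the attainable
  range in every generated table.
* **Responses**: a latent diet-poorness trait (shifted upward for men
  and current smokers, inducing realistic confounding) loads on the
  standardized item score and steers an ordered-threshold choice model;
  propensities evolve as an AR(1) process across visits
  (autocorrelation 0.7). Item popularity is tilted toward healthy items
  (the Mediterranean base diet), and the trait loadings are centred
  against energy-weighted consumption probabilities so the trait shifts
  diet *composition* rather than total volume. A latent consumption
  shift for men yields higher male energy intakes. The frequency-level
  marginals, portion scale and popularity tilt were calibrated once so
  that baseline energy means sit near 2,000/2,300 kcal/day (women/men),
  the DI distribution is unimodal with mean ≈ 3.5, and the implausible-
  energy filter removes ≈ 5% — the conditions the analysis pipeline is
  meant to face.
* **Survival**: piecewise-exponential cause-specific hazards over the
  inter-FFQ periods, `base_rate × exp(β · z + covariate LP + frailty)`,
  with `z` the current cumulative-average DI standardized by the
  cohort's baseline mean and SD. Event times are exact inverse-CDF
  draws within each period; the first event wins. Cluster frailty is a
  shared log-normal multiplier per household (variance 0 by default —
  no cluster details are settled, so correlation is opt-in).

What the generator does **not** emulate: the joint correlation structure
of real food consumption (items are conditionally independent given the
trait), seasonal or secular diet drift, differential FFQ measurement
error, covariate missingness, and any intervention effect. Passing
recovery tests therefore demonstrates that the pipeline estimates what
the generator encodes — a necessary check of the machinery, not evidence
about any real cohort.

## 5. Test problem sizes and statistical tolerances

The test suite checks algebraic identities on randomized inputs (1,000
dietary-index records; 200 random profiles against an independent
componentwise oracle; every threshold boundary ± 1e−9) and calibrates
the statistical machinery by simulation: parameter recovery on 200
replicates of n = 2,000 cohorts with 4 annual FFQs at a true per-SD CVD
hazard ratio of 1.4 (mean estimate within 3 Monte-Carlo SEs of truth,
95% CI coverage within the exact binomial interval), and type-I error of
the trend test and interaction LRT on 400 null replicates of n = 1,000
(rejection counts within the exact binomial 95% interval at α = 0.05).
These sizes were chosen as the smallest at which the Monte-Carlo noise
floor is meaningfully below the effects being verified.

## 6. Known limitations

* The threshold tables are a transcription of the official 2023
  algorithm; the beverage sweetener component is not implemented because
  the nutrient profile deliberately carries no sweetener field.
* Scored beverages span four letter classes (B–E) by construction — A
  is water-only — so "five classes over the attainable range" holds for
  the solid-food categories.
* The trend test uses Wald p-values from robust fits; with very few
  events per quintile its calibration degrades, and `fit_cox` flags
  quintiles with zero events as unstable rather than dropping them.
* Fine–Gray estimates use the same covariate sets as the cause-specific
  models; covariate effects on the subdistribution scale are not
  comparable one-to-one with cause-specific hazard ratios.
* Complete-case handling only: rows with missing covariates are the
  caller's responsibility (`coxph` drops them with its usual warnings).
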