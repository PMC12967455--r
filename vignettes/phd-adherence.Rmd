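---
title: "Measuring Planetary Health Diet adherence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Planetary Health Diet adherence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phdiet)
```

## The problem

The EAT-Lancet Planetary Health Diet (PHD) defines reference intakes, at a
2500 kcal/d energy level, for around fourteen food groups: plant foods to
encourage (whole grains, vegetables, fruits, legumes, nuts, unsaturated
oils), animal foods to moderate (dairy, fish, poultry, eggs) and foods to
limit (red meat, tubers, saturated fats, added sugars). Judging how closely
a surveyed population eats to this pattern requires reconciling three
awkward features of dietary survey microdata: much of the intake arrives as
composite dishes rather than food groups; participants eat at very
different energy levels; and survey samples are demographically skewed
relative to the national population. `phdiet` addresses each stage
explicitly and then scores adherence at the individual level.

## Recipe disaggregation

Each composite dish carries a standardised formulation: the fraction of the
dish weight contributed by each food group. Disaggregation is linear — a
dish of weight $w$ with proportion $p_g$ for group $g$ contributes
$w \, p_g$ grams to $g$ — and proportions need not sum to one; the
remainder (water, broth, unclassified mass) stays outside the food-group
system, including energy accounting. Mass is therefore conserved as an
inequality: allocated grams never exceed consumed grams, with equality only
for fully classified, ungated dishes.

Two conventions matter:

* **Gating.** An encouraged ingredient inside an unhealthy preparation is
  not credited to its group (a sweetened "whole-grain" cereal yields added
  sugars but no whole grains). The gate is a curated per-line flag in the
  recipe database, not a run-time inference: deciding which preparations
  are unhealthy requires judgement (sugar thresholds, fat quality) that no
  general rule captures, so the flag records the curator's decision.
  Gating only ever withholds credit from encouraged groups — the validator
  reports a gated limited-food line as an error.
* **Unknown dishes.** Default behaviour is to fail (strict mode) with a
  typed condition carrying the dish id; lenient mode drops the dish. Silent
  data loss is worse than a crash in a harmonisation pipeline, so lenient
  mode is opt-in.

Intakes are summed within each recall day and averaged, unweighted, over a
participant's distinct recall days. Surveys contribute between two and four
recall days; with no principled day weighting available, days count
equally.

## Harmonisation

* **Energy standardisation.** Intakes are rescaled to grams per 2500 kcal
  using the participant's mean daily energy (per-day energy is not used:
  the adherence unit is the participant). The operation is idempotent at
  the reference energy.
* **Misreporting exclusion.** Participants with implausible energy —
  outside 800–4200 kcal/d (men) or 600–3500 kcal/d (women) — are excluded
  before any scoring. The bounds are stated as strict inequalities, so
  boundary values are retained. Fixed kcal cut-offs are a deliberate,
  simple choice; Goldberg-type EI:BMR methods need anthropometry that
  harmonised food-group extracts rarely carry.
* **Post-stratification weights.** Within each country, participant $i$ in
  age×sex stratum $s$ receives $w_i \propto P_s / \hat{p}_s$ (population
  share over sample share), rescaled so $\sum_i w_i$ equals the country's
  sample size. This convention keeps effective sample sizes comparable
  across countries and makes the weighted age×sex margins match the
  population exactly. Education is *not* used in weighting — it enters
  only as a regression covariate, with an explicit `missing` state for
  surveys that never collected it.
* **Pooling.** European summaries weight each country by its national
  population share among included countries, so the pooled mean is a convex
  combination of country means.

## The three indices

All scoring operates on energy-standardised intakes against the target
table (`phd_targets()`, shipped editable as
`inst/extdata/phd_targets.csv`).

**Compliance** is $100 \times \text{intake}/\text{target}$ per food group:
100% is on-target, above/below 100% is over/under-consumption. It is
deliberately unbounded and direction-agnostic; interpretation depends on
whether the group is encouraged or limited.

**WISH** scores 13 groups (red meat as a total; tubers unscored) on
piecewise-linear curves clamped to $[0, 10]$:

* `ramp_up` (encouraged foods): 0 at zero intake, rising linearly to 10 at
  the full-compliance breakpoint, then flat.
* `ramp_down` (limited foods): 10 up to the lower breakpoint, falling
  linearly to 0 at the upper one.
* `plateau_range` (foods to moderate): 10 across the recommended range,
  with linear flanks on both sides.

**ELI** grades 14 components (red meat split into beef/lamb and pork;
tubers scored; saturated fats not separately scored) on a 0–3 scale over
three cut-points. Emphasised foods score higher in higher intake bands,
limited foods the reverse. An intake exactly on a cut-point takes the
higher-adherence side, matching the inclusive-threshold reading of graded
scales. Note that ELI classifies dairy among the limited components while
the ELD-I sign convention treats dairy as encouraged; the target table
therefore carries both a `direction` and an `eli_direction` column.

**ELD-I** is the signed relative deviation
$s_g = d_g (x_g - t_g) / t_g$ with $d_g = +1$ for encouraged and $-1$ for
limited groups, summed over 14 groups (red meat as a total). It is exactly
linear in intake with slope $d_g / t_g$, zero at perfect adherence, and
unbounded — 100 g/d of red meat against the 28 g target contributes
$-(100-28)/28 \approx -2.6$ alone. The uncapped linear form is the
default; because all scoring parameters live in the target table, a capped
or rescaled variant can be substituted without touching code. The linearity
is also what makes the generator's demographic effects analytically
checkable (below).

### Provisional scoring parameters

The PHD targets and ranges in the default table are the standard reference
values (whole grains 232, vegetables 300, fruits 200, tubers 50, legumes
75, nuts 50, unsaturated oils 40, dairy 250, red meat 28 = 14 + 14,
poultry 29, eggs 13, fish 28, saturated fats 11.8, added sugars 31 g/d at
2500 kcal). The WISH breakpoints and ELI cut-points beyond those anchors
are package defaults derived from the targets — `ramp_up` reaches 10 at
the target, `ramp_down` reaches 0 at four times the target, ELI bands sit
at {0.25, 0.5, 1}× target for emphasised and {1, 2, 4}× target for limited
foods — because the source indices publish their exact tables in
supplementary material not reproduced here. They are flagged provisional:
analyses that depend on absolute WISH/ELI levels (rather than orderings or
bounds) should review `phd_targets()` first.

## Cohort analytics

* **Deviation tests.** A country's departure from the pooled mean is
  tested with a weighted intercept-only regression of centred values — a
  weighted one-sample test. Survey design variance (clustering, replicate
  weights) is out of scope, so standard WLS inference is used and stated
  as such.
* **Heterogeneity.** Cochran's $Q$ on inverse-variance weights,
  $I^2 = \max(0, (Q - df)/Q) \times 100$, and the DerSimonian–Laird moment
  estimator for $\tau^2$ — the simplest standard random-effects choice,
  cross-checked against `metafor::rma(method = "DL")` in the test suite.
* **Dominance analysis.** The general dominance weight of predictor $j$ is
  its Shapley-style average incremental $R^2$ over all subsets of the other
  predictors, computed from weighted cross-products (each subset is a small
  linear solve, not a full `lm()`). Weights sum to the full-model $R^2$ to
  1e-9 by construction; the suite verifies this on random fixtures and
  against a brute-force `lm()` oracle. Exhaustive enumeration runs up to 16
  predictors ($2^{16}$ subsets); beyond that a seeded random-ordering
  sampler reports Monte-Carlo standard errors. Constant components (zero
  variance) are dropped before decomposition and recorded in the report.
* **Demographic regressions.** WLS of each index on dummy-coded age band,
  sex, education and their pairwise interactions, fitted per country;
  reference levels are 18–44, women, lower education. Coefficients are
  reported on the raw point scale and with the outcome z-scored by its
  weighted mean/SD (dummies stay 0/1, so standardised coefficients remain
  interpretable as SD-scaled group differences). Effect sizes are
  classical $\eta^2 = SS_{\text{effect}}/SS_{\text{total}}$ from Type II
  sums of squares, labelled small/moderate/large at 0.01/0.06/0.14.
  Countries without education data are fitted without that factor.
* **Concordance.** Pearson correlations between the index totals (weighted
  and unweighted are both emitted, since either convention is defensible)
  and quintile agreement: quintiles are assigned by rank with ties broken
  by stable input order — unweighted, because rank-based assignment is the
  only convention that reproduces exactly under ties.

## The synthetic generator

`phd_sim_config()` encodes the statistical structure the analytics assume,
emulating a harmonised nine-country European survey:

* **Marginals.** Individual standardised intakes are log-normal
  (non-negative, right-skewed — the typical shape of dietary data), with a
  within-country coefficient of variation of 0.6 and groups independent by
  default (no covariance information is available to calibrate against).
* **Calibration.** Group means are centred on pooled European values
  (e.g. vegetables 189.6 g/d, fruits 177.1, whole grains 31.5, red meat
  40.4 + 42.0, added sugars 54.6); the accompanying SDs parameterise the
  *between-country* spread of country means (drawn log-normally,
  mean-preserving). This reading of the spread is a modelling choice: it
  reproduces the empirically observed regime in which nearly all
  between-country variance is real heterogeneity ($I^2 > 95\%$), and
  setting `country_spread = 0` collapses it for negative controls.
* **Demographics.** 56.1% women; age shares 39.8/35.7/24.5% for
  18–44/45–64/≥65; education 59.3/40.7% lower/higher, with two countries
  lacking education entirely. Population margins deliberately differ from
  the sample mix so post-stratification weights are non-trivial.
* **Effects.** Demographic contrasts are additive g/d shifts on
  adherence-relevant groups (men eat more red meat, added sugars and
  saturated fats and fewer plant foods; older and higher-educated
  participants the reverse). Magnitudes were chosen once at a moderate,
  direction-consistent scale. Because ELD-I is linear, the implied index
  contrast is exactly $\sum_g d_g \delta_g / t_g$;
  `expected_eldi_contrasts()` computes it and `truth.json` ships it with
  every dataset, making parameter-recovery tests self-verifying.
* **Energy and misreporters.** Truncated-normal energy inside the
  sex-specific plausibility bounds (women 1900 ± 350, men 2400 ± 450
  kcal/d), with a 1.6% misreporter fraction forced outside the bounds, so
  exclusion counts are binomially predictable. Raw intakes are the
  standardised draws rescaled by energy/2500, which makes standardisation
  exactly invertible.
* **Dish routing.** A quarter of participants have half of their
  compatible intake re-expressed as daily sandwich-dish records, with the
  allocation subtracted from their direct intakes — so the recipe engine is
  exercised end to end while disaggregation-plus-recombination reproduces
  the drawn intake exactly.

What the generator does **not** emulate: within-person day-to-day variance
(usual-intake modelling is out of scope), intake correlations across food
groups, survey design clustering, item non-response, and coding-system
idiosyncrasies. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly under the stated model, not that any real
population resembles the synthetic one.

## Numerical conventions

* Exclusion boundaries are inclusive (strict-inequality reading).
* ELI cut-point ties go to the higher-adherence score.
* WISH outputs are clamped to $[0, 10]$ after curve evaluation.
* Dominance subset solves fail loudly on exact collinearity, naming the
  offending subset.
* All randomness flows from a single integer seed; identical seeds yield
  byte-identical output trees (verified via manifest MD5 checksums).
* Table I/O snaps doubles to 12 significant decimal digits on write and
  re-snaps after parsing (`phd_write_csv()` / `phd_read_csv()`), because
  the fast CSV parser is not correctly rounded at full double precision;
  12 digits make write–read–write cycles byte-stable while far exceeding
  the statistical resolution of every emitted quantity.

## Test problem sizes

The suite exercises: worked-example anchors (instant); bound checks on
10^4 random diets; dominance decompositions on 100 random fixtures with
2–14 predictors; heterogeneity on the default nine-country cohort of
9 × 500 participants; and parameter recovery over 100 generated surveys of
9 × 500, checking that the per-country regression CIs cover the analytic
ELD-I contrasts at their nominal rate. These sizes give Monte-Carlo noise
well below every asserted tolerance while keeping the default test run in
the low minutes.

## Known limitations

* WISH/ELI absolute levels depend on provisional curve parameters (above).
* ELD-I's uncapped linearity lets a single extreme group dominate a total;
  reported component tables make such cases visible.
* The deviation and regression inference is model-based WLS; with true
  survey designs (PSUs, replicate weights) it will understate variance.
* Education is harmonised to two levels plus `missing`; finer gradients
  are collapsed.
* Quintile agreement between *negatively* correlated indices is not 0 but
  20% (the middle quintile maps to itself under reversal) — worth
  remembering when reading concordance tables.
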