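---
title: "Developing an HPF screening questionnaire: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing an HPF screening questionnaire: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqhpf)
```

This vignette is the package's account of the science behind
`sqhpf_develop()`: the statistical model at each stage, the conventions we
chose where the methodology is genuinely open, what the synthetic-cohort
generator does and does not emulate, and the limitations that follow.

## The development pipeline

### From FFQ answers to quantities

A semi-quantitative FFQ offers nine frequency categories per item, from
"never or hardly ever" to "more than 6 times a day". The conversion to a
daily rate is not part of the questionnaire itself; we use the standard
Willett-style category midpoints

| index | category | times/day |
|---|---|---|
| 0 | never or hardly ever | 0 |
| 1 | 1–3 times/month | 2/30.44 |
| 2 | once a week | 1/7 |
| 3 | 2–4 times/week | 3/7 |
| 4 | 5–6 times/week | 5.5/7 |
| 5 | once a day | 1 |
| 6 | 2–3 times/day | 2.5 |
| 7 | 4–6 times/day | 5 |
| 8 | more than 6 times/day | 7 |

(months taken as 30.44 days). The grid is configurable in
`ffq_frequency_grid()` but every default in the package assumes these
anchors. Grams/day per item is portion × rate; the fried-foods item has no
standard portion and is carried as frequency only — it can be *selected*
and *scored*, but contributes no mass to any gram-based share.

### The tertile-agreement outcome

Each classification system marks different items as HPF (NOVA group 4,
IARC group 3, IFIC groups 4–5, UNC groups 4.1–4.2), so no single system
can define "the" high-HPF consumer. The development outcome instead uses
agreement between systems: per system, participants are split at the
empirical 1/3 and 2/3 quantiles of HPF%; a participant is a case (1) when
in T3 under at least two systems (and not T1 under two), a control (0) in
the mirror situation, and excluded otherwise. Exclusions run in flowchart
order: energy plausibility, then missingness, then tertile agreement, with
counts logged at each step.

Two conventions are ours because the methodology leaves them open: tertile
cuts use type-7 (linearly interpolated) empirical quantiles, and values
tied with a cut go to the *lower* tertile. Both make the assignment
deterministic and order-independent; the tie rule also sends a fully
degenerate (constant) vector to T1 rather than failing.

### Item selection

One binomial logistic regression per candidate — not a joint model —
regresses the 0/1 outcome on the candidate's frequency (times/day), always
adjusted for age, sex, recruitment center, energy intake, physical-activity
level, blood-pressure and diabetes medication, working status, education
and civil status. Categorical covariates are dummy-coded against the
alphabetically first level. The fitter is a plain IRLS (zero start,
convergence when the largest coefficient step is below 1e-8, at most 50
iterations) with Wald z-tests; complete separation is detected as a slope
exceeding 15 on its standardized-predictor scale and reported as an
explicit error rather than a huge "significant" coefficient. Bonferroni
correction uses the number of candidates tested (33 under the default
layout: 30 food groups plus binge eating, binges/week and snacking);
selection requires β > 0 *and* adjusted p < 0.05 — the sign rule means
protective (healthy) groups can never enter the screener however
significant they are.

### Cutpoints on the answer grid

For each selected group, ROC analysis of group frequency against the
outcome uses the observed unique values as candidate thresholds (positive
call at-or-above the threshold) and picks the one maximizing the Youden
index, ties to the smallest threshold. A criterion must be answerable on
the FFQ, so the continuous optimum is rounded **up** to the first category
whose rate reaches it: the fielded criterion is at least as strict as the
optimum. Category 0 ("never") is never a criterion — a threshold of zero
maps to category 1, i.e. any consumption at all. Display strings are
rendered in the category's natural period (e.g. "≥ 2 t/week" for the
2–4/week category, "> 3 t/month" for once a week), reproducing the mixed
">"/"≥" phrasing such questionnaires print. For scoring, a group-level
answer is the summed times/day of its member items re-binned to the nearest
grid category, consistent with selection operating on summed group
frequency; single-item groups reduce to the item's own answer.

### Psychometric validation

The factor analysis is deliberately old-school: unrotated principal-axis
factoring on the Pearson correlation matrix of the 14 binary item
indicators, squared multiple correlations as initial communalities,
iterated to a 1e-6 tolerance with at most 100 iterations, Heywood
communalities clipped at 1 with a warning, and factor signs fixed so each
loading column sums positive. Retention follows Kaiser's criterion
(eigenvalues of the *unreduced* matrix strictly above 1). Binary indicators
with Pearson correlations understate associations relative to tetrachoric
ones, so loadings are conservative; `sqhpf_develop(efa_input =
"frequency")` runs the same analysis on the continuous group frequencies
instead. Sampling adequacy is the Kaiser–Meyer–Olkin MSA from anti-image
partial correlations; sphericity is Bartlett's χ² = −(n − 1 − (2p + 5)/6)
ln|R|; internal consistency is standardized Cronbach's α = k·r̄ / (1 +
(k − 1)·r̄).

Agreement between score tertiles and each system's HPF tertiles uses
weighted Cohen's κ with linear disagreement weights |i − j|/(k − 1) by
default; the weighting is a flag (`kappa_scheme`) because published
agreement analyses frequently leave it unstated, and quadratic weights are
reported alongside when asked. The standard error is the large-sample
delta-method form.

### Calibration

The FFQ-derived questionnaire HPF% (grams from the selected groups over
total grams) is regressed on the score by OLS. The published instrument's
line — HPF% = 3.7·score + 7.6 — is shipped as `published_calibration()`,
kept distinct from any freshly fitted model; every report states which
model produced an estimate. The equivalency table rounds to one decimal
and prints whole numbers bare ("15", not "15.0").

## The synthetic-cohort generator

Real development cohorts of this kind are restricted-access, so the
package carries its own: `generate_cohort()` draws, per participant, a
latent HPF propensity θ ~ N(0, 1) and, per item, a continuous rate
`base · (1 + dir · effect · θ) + noise`, truncated at zero and discretized
to the nearest grid category. The default layout plants 14 HPF-positive
groups (direction +1), 11 healthy groups (−1) and 5 neutral groups (0)
across 143 items; the default effect size of 0.35 per SD of θ and
item noise of 0.8 × baseline give covariate-adjusted selection z-statistics
comfortably past the Bonferroni threshold at cohort scale without
approaching separation, which is what a well-powered development cohort
looks like. Covariates are drawn conditionally on θ in the directions seen
in such cohorts (male, younger, higher-energy, actively working → higher
propensity); ages are truncated to 55–75 and energies to realistic windows
so that the energy filter trims only a handful of records. Items of
planted groups are labelled HPF under each system independently with
probability 0.9 (`label_overlap`), which makes the four systems agree
strongly but not perfectly; at `label_overlap = 1` they coincide exactly
and all pairwise κ equal 1.

Two structural facts about this design are worth knowing when reading test
results. First, a group's consumption enters the outcome *mechanically*
through the HPF-share fraction — planted groups through the numerator,
every mass-bearing group through the denominator — so even a zero-effect
neutral group shows a small negative association, and a zero-effect
*planted* group would still show a positive one. True null associations
exist only for predictors outside the share altogether (the habit
variables, near-massless groups). The sign rule makes this harmless for
selection. Second, the generator emulates structure, not nutrition: it has
no seasonal terms, no nutrient correlations, no item-level portion
heterogeneity beyond a fixed jitter, and its portion sizes are invented
placeholders. Passing tests therefore demonstrate that the pipeline's
statistics behave as designed, not that the synthetic questionnaire is
field-valid.

`generate_calibration_data()` emulates the final stage in isolation
(scores binomial on 0–14, percentage = 7.6 + 3.7·score + N(0, 5)), so
calibration recovery can be checked against the published equation
independently of the upstream stages.

## Problem sizes and determinism

Everything is seeded through `synthetic_config(seed =)` or explicit seeds;
identical configs give byte-identical cohorts and fits. Unit tests run at
n = 60–3000; the end-to-end recovery study uses 20 replicate seeds at the
development-cohort scale of n = 4400, which completes in well under a
minute since each replicate is a single pass of vectorized generation plus
33 IRLS fits. `scripts/acceptance.R` uses one seed at n = 4400 per
quantity.

## Interface notes and limitations

The package exposes one fitting function, `sqhpf_develop()`, returning a
classed object with the usual modelling methods (`print`, `summary`,
`coef`, `predict`, `plot`, `residuals`, `fitted`); the stage functions are
exported individually for scripted use, which together with
`write_sqhpf_report()` replaces any shell-level driver. Known limitations:
no tetrachoric correlations or factor rotations; no penalized or Firth
logistic fallback under separation; κ confidence beyond the large-sample
SE is out of scope; the longitudinal behaviour of a fitted screener
(repeat administrations) is not modelled; and none of the shipped
classification assignments or portion sizes should be mistaken for the
published instrument's restricted source data.
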