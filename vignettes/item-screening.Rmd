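---
title: "Phase-III item screening: model, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-III item screening: model, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlqscreen)
```

## The problem

In the EORTC tradition of questionnaire module development, a provisional
item list is field-tested on a small, deliberately heterogeneous patient
cohort before psychometric validation: every patient completes the
provisional questionnaire and is then debriefed about items that were
upsetting, difficult to understand, especially relevant, or missing.
qlqscreen implements the quantitative side of that pretesting stage for
1--4 Likert instruments, built around the field test of the QLQ-AA/PNH
module for aplastic anaemia (AA) and paroxysmal nocturnal haemoglobinuria
(PNH): 48 patients, 69 provisional items.

The pipeline behind `item_screen()` is

1. recode reverse-worded items, `x -> 5 - x`, so higher always means more
   problems (`recode_reverse()`);
2. per-item descriptive statistics (`compute_item_stats()`);
3. the eight-criterion retention screen and keep rule
   (`evaluate_criteria()`, `screen_decision()`);
4. missing-issue screening of the debriefing interviews
   (`missing_issue_screen()`);
5. Cronbach's alpha of the hypothesised scales (`scale_report()`);
6. reconciliation with the recorded expert decisions
   (`apply_group_decisions()`).

## Statistics and their denominators

For every item we report the mean and observed range over the non-missing
responses, the fractions of the cohort scoring in the lower (1--2) and
upper (3--4) halves, the completion rate, and the three debriefing
fractions. Two denominator conventions interlock:

* **Category and debriefing fractions use the enrolled cohort.** A missing
  response counts in neither half, so `frac_low + frac_high == completion`
  — and the package makes that identity bit-exact by computing completion
  as the sum of the two category fractions. The convention is forced by the
  reference table itself, where the two category fractions sum to the
  printed completion in every row (e.g. item s68: 0.38 + 0.30 = 0.68).
* **Item means use completers only.** A cohort-wide denominator would push
  the mean of a low-compliance item below the scale minimum, contradicting
  the printed means (s69: mean 2.2 at completion 0.43).

Whether the published debriefing fractions used all 48 enrolled patients or
only item completers was never documented; the package uses
the enrolled cohort for both, which is the only convention consistent with
the category-fraction accounting above. Fractions are kept at full
precision internally; rounding to two decimals happens only in
`render_table()`.

Cohort characteristic summaries round percentages half away from zero
(21/48 becomes 44%), matching the published sample table.

## The retention criteria

An item's statistics feed eight a-priori criteria (thresholds all live in
`criteria_thresholds()` and are configurable; the defaults are the
field-test values):

| | criterion | default rule |
|---|---|---|
| c1 | relevance | mean > 1.5 |
| c2 | relevance | > 50% score 3 or 4 |
| c3 | no floor/ceiling | > 10% in each half |
| c4 | range | observed responses span 1..4 |
| c5 | acceptability | < 5% find it upsetting |
| c6 | easiness | < 5% find it difficult |
| c7 | compliance | > 95% complete it |
| c8 | priority | >= 2% name it especially relevant |

The inequality directions are deliberate: c1--c7 strict, c8 non-strict,
exactly as the rules were stated for the field test; boundary rows in the
reference table (item s08 passes compliance at 0.96 > 0.95, item s34 fails
easiness at difficult = 0.05) pin both directions. The screen keeps an
item when **at least five of c1--c7 hold, or c8 holds** — a monotone rule,
which the test suite checks by flipping individual flags. The engine never
deletes anything itself: the final roster comes only from recorded expert
decisions, which may override the screen with stated arguments. With the
published decisions, 14 screen-passing items were nonetheless deleted
(redundancy arguments), and both screen failures were deleted too,
yielding 47 keeps, 16 deletions, 5 changes and 1 expansion — 54 items.

Degenerate items (zero completion) fail c1--c4 and are marked
`degenerate` rather than raising, so screening completes on arbitrary
cohorts.

### The printed flags are data

The packaged reference table stores the published per-item fractions
*and* the published criterion flags side by side, and
`qlq_aapnh_phase3()` never recomputes the latter from the former. The
published fractions are rounded to two decimals, and one row (s69,
upsetting printed as 0.05 with its acceptability flag set) sits exactly on
the rounded boundary of the strict rule: its unrounded value was evidently
below 0.05, but that information is lost in printing. Recomputing flags
from the printed fractions therefore reproduces all 69 rows except s69's
acceptability flag (and hence its verdict); the test suite asserts exactly
this known divergence rather than silently "resolving" it.

## Internal consistency

`cronbach_alpha()` implements
$$\alpha = \frac{k}{k-1}\Bigl(1 - \frac{\sum_i s_i^2}{s_T^2}\Bigr)$$
with sample (n−1) variances over listwise-complete patients. Listwise
deletion is the conventional default for alpha and the only implemented
policy; the `missing` argument leaves room for alternatives. Alpha is
undefined — reported as `NA`, never fabricated — when fewer than three
complete patients remain or the total score has zero variance;
`scale_report()` turns such rows into `NA` entries instead of aborting.

The published scale alphas (0.63 for social support up to 0.92 for fear of
progression and illness intrusiveness) are **not reproducible** from this
package: the raw responses and the scale memberships were never deposited.
They are recorded here as context only. The published phrasing is read as
two scales sharing the maximum of 0.92 rather than one combined scale;
nothing downstream depends on that reading because memberships are
configuration (`read_scales()`), not code.

## The cohort simulator

`simulate_cohort()` exists so every downstream stage is testable without
patient data. Its generative model is the minimal structure that makes
"hypothesised scales" and alpha meaningful and analytically checkable: a
single factor per scale with homogeneous loading. For patient $p$ and item
$i$ in scale $s$,
$$x_{pi} = \mu_i + \lambda_s F_{ps} + \sqrt{1-\lambda_s^2}\,\varepsilon_{pi},$$
with $F_{ps}, \varepsilon_{pi}$ independent standard normal, so the
continuous scores of a $k$-item scale have common inter-item correlation
$r=\lambda_s^2$ and population alpha $kr/(1+(k-1)r)$ (Spearman–Brown,
exposed as `spearman_brown_alpha()`). The ordinal response is the category
of $x_{pi}$ under strictly increasing cut points (default $-1, 0, 1$ on
the standardised scale), whose category masses are normal-CDF differences
(`category_masses()`). Reverse-coded items are emitted on the reversed raw
scale, so the pipeline genuinely has to recode them. Responses are then
masked completely at random per item; debriefing flags are independent
Bernoulli draws; completion times are rounded, range-clamped log-normal
draws. One RNG stream per cohort, seeded explicitly: the same seed gives
byte-identical output.

`default_cohort_config()` pins the defaults to the study conditions rather
than to round numbers: 48 patients; the 69 items with the published
reverse-coded set {s25, s27, s45, s46, s49, s66, s67, s68}; per-item
missingness $1-$ published completion; per-item debriefing probabilities
equal to the published fractions; per-item latent means inverted with
`uniroot` (tolerance $10^{-9}$ on $[-6,6]$, where the expected category
mean is strictly increasing in $\mu$) so the expected recoded mean matches
the published item mean; and loadings inverted from the published alphas
via Spearman–Brown under a fixed synthetic 11-scale grouping
(`qlq_aapnh_scales()`), since the true memberships are unpublished.

What the simulator deliberately does **not** emulate: informative
missingness (only compliance was published, no mechanism), dependence of
debriefing flags on responses, response styles, differential item
functioning, or the mid-study wording reordering (the cohort is treated as
homogeneous). Passing tests on simulated cohorts therefore demonstrate
algorithmic correctness under a clean MCAR single-factor world, not
robustness to those real-data features.

## Numerical choices and problem sizes

* Strictness of every inequality follows the stated rules verbatim; ties
  are therefore decided by the rule, never by tolerance fudging.
* Percent rounding is half-away-from-zero; fraction rounding happens only
  at rendering.
* Alpha uses n−1 variances; the test suite pins the choice against an
  independent covariance-matrix oracle at $10^{-12}$.
* Monte-Carlo checks in the tests use $n = 5\,000$ for alpha recovery
  (±0.03 of the closed form) and $n = 10\,000$ for category masses
  (±0.02), missingness concentration and independence checks — sizes at
  which binomial standard errors are comfortably inside the asserted
  tolerances while the whole suite runs in seconds.

## Limitations

The screen encodes the published decision *rules*; the expert judgement
they informed (redundancy arguments, clinical experience) enters only as
recorded `group_decisions()`. No similarity metric between near-duplicate
items is implemented, no imputation is performed, and item-total
correlations, alpha-if-item-deleted and alpha confidence intervals are out
of scope for the pretesting stage this package serves.
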