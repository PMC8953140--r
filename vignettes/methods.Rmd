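---
title: "Methods: claims-based case-control analysis of maternal factors for neonatal jaundice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jaundiceclaims)
```

## Design

The package implements a retrospective case–control design on longitudinal
claims. The unit of analysis is a *delivery case*, not a woman: a woman with
several deliveries contributes several independent cases, and may appear in
both the jaundice and control groups across deliveries. Cases are deliveries
whose mother carries a neonatal-jaundice code within 4 weeks after delivery
(jaundice treated before birth registration is billed on the mother's
insurance); controls are all other analyzable deliveries. Exposures are
3-character diagnosis-code categories observed in one of two windows:
antenatal care (study A) or the year before the pregnancy diagnosis
(study B).

## Temporal rules and their parameters

All week/year rules convert to days once and are used everywhere as closed
intervals:

| rule | value | role |
|---|---|---|
| flag window | 28 d (4 wk) | delivery-adjacent flags (preterm, multiple gestation), post-delivery jaundice/stillbirth window, minimum delivery-to-next-pregnancy gap |
| inter-delivery gap | 168 d (24 wk) | a delivery-coded date ≥ 168 d after the current event's anchor starts a new event (periviable-birth bound) |
| maximum gestation | 308 d (44 wk) | pregnancy claims further than this before delivery cannot belong to the episode |
| pre-conception window | 365 d | study-B exposure window |

Event grouping is greedy and **anchored at the event's first date**. The
alternative (chaining: compare to the last date seen) is order-dependent in
pathological inputs; anchoring makes the partition unique and independent of
row order, which the suite asserts by shuffling inputs.

Decisions taken where the design was open:

* The delivery-mode search reuses the ±28 d window (no window is otherwise
  stated); any cesarean code (O82, O84.2) beats any vaginal code.
* The abortion/stillbirth exclusion window is `[pregnancy dx, delivery+28]`:
  only codes attributable to *this* episode disqualify it. An abortion code
  from years earlier should not delete a later healthy pregnancy.
* "Qualification incomplete" means: no qualification row for the
  pregnancy-diagnosis year or the delivery year — the minimal reading of
  incomplete coverage around gestation.
* A missing delivery-year qualification row also means the age at delivery
  is unknown; such cases fall at the qualification stage, not the age stage,
  keeping the cascade order fixed.
* Maternal age uses the delivery year's 5-year qualification band, mapped to
  the three analysis bands (15–24, 25–34, 35–49) by band midpoint.
* Income rank 0 (medical aid) folds into the lowest of the five 20 % income
  groups: {0,1,2}→1, {3,4}→2, {5,6}→3, {7,8}→4, {9,10}→5. The fold is an
  argument of `income_group5()` because the original grouping is not fully
  specified.
* Study-B eligibility mirrors study A's on the study's own window: a case
  needs at least one non-pregnancy-related code in the window it is analyzed
  in. (The alternative — requiring an ANC record for study B too — is a
  plausible reading; it is not the default because eligibility should be a
  property of the analyzed window.)
* Codes in the pregnancy-related exclusion set (chapter O, Z32–Z39) define
  the ANC context and are never *tested* as exposures in study A; in study B
  they are testable, since there they are history, not context.

## Exact inference

`fisher_2x2()` conditions on both margins of the 2×2 table. With `a`
exposed cases, margins `m = a+c` (exposed), `k = a+b` (cases), the count A
follows Fisher's noncentral hypergeometric distribution with odds ratio ψ.
The package reports:

* **p**: two-sided minimum-likelihood rule at ψ = 1 — the sum of
  probabilities of all tables at most as probable as the observed one;
* **OR**: the conditional MLE solving `E_ψ[A] = a` (0 or ∞ when `a` sits at
  an end of its support);
* **CI**: `P_ψhi(A ≤ a) = 0.025`, `P_ψlo(A ≥ a) = 0.025`.

The CMLE is *not* the sample cross-product ratio; in sparse tables the two
differ visibly (212.33 vs 213.57 in the worked example), and published
values pin the convention.

One numerical subtlety is deliberate: roots are located on the ψ scale over
(0, 1), or the reciprocal scale for roots above 1, at `uniroot`'s default
tolerance — the convention of the exact-test implementation this field's
reported values come from. A fully converged root differs in the third
significant digit for extreme tables (213.28 for the example above); since
the reported estimate is defined by convention, the package reproduces the
convention, and the test suite checks both this and agreement with
`stats::fisher.test` to 1e-8 on ordinary tables. The p-value itself is
checked against full hypergeometric enumeration for *every* 2×2 table with
N ≤ 60.

The r×c exact test (used for the multi-level demographic contrasts) is
estimated by seeded Monte Carlo over margin-fixed tables (Patefield
sampling); its estimate carries a standard error and the suite compares it
to the exact 2×2 p within 3 SE. The t statistic for ANC duration is Welch's
(safer than pooled when group variances differ, as they do here), and the
income trend uses the Cochran–Armitage statistic with scores 1..k.

## Matching and stability selection

The propensity score is the fitted probability of case status from a
logistic regression on age band (3 levels) and income group (5 levels) —
the two design covariates, nothing else. The model is fitted once on the
full sample: shuffling affects only matching order, not the scores.
Complete separation (a covariate cell predicted case with certainty) is an
error; cells without cases are harmless and keep score ≈ 0.

Matching is greedy 1:10 nearest neighbour on the raw score without
replacement: records are shuffled, cases processed in shuffled order, each
taking the 10 closest available controls, distance ties resolved by shuffled
position. With only 15 distinct covariate cells, scores are heavily tied —
the shuffle is what makes the 1,000 repetitions non-degenerate, so the
tie-break is part of the algorithm's contract and is tested against an
exhaustive O(n²) replay. The C++ implementation keeps controls sorted by
(score, shuffled rank) with union-find next/prev-available pointers, making
each pick amortized near-constant.

Per repetition, a code is significant when its exact CI excludes 1 *and*
p < 0.05. Aggregation over repetitions: significance count, mean OR over
significant repetitions with finite OR (infinite ORs counted separately,
never averaged), mean p over significant repetitions, mean exposed counts
over all repetitions. A code is a risk (protective) factor when significant
in strictly more than 90 % of repetitions with mean OR above (below) 1 and
mean p < 0.05. The 0.9 fraction scales to reduced `n_reps` so that
simulation studies can run at 200 repetitions; at the production 1,000 it is
exactly the "more than 900" rule.

Adjusted odds ratios come from conditional logistic regression per matched
repetition — exposure, preterm, cesarean, multiple gestation, ANC duration
(per day) — maximized by damped Newton on the stratified conditional
likelihood with Wald CIs from the observed information, and aggregated over
the repetitions where the univariable test was significant. Refitting per
repetition (rather than on a single matched sample) is implied by the
aggregation layout of the reference results, where the nuisance-covariate
ORs vary slightly across disease rows. `survival::clogit` and a dense
grid-search likelihood oracle independently confirm the fitter.

## The synthetic cohort

`generate_dataset()` emulates the source layout: a qualification table
(person-year rows with sex, 5-year age band, income rank 0–10), a statement
table (principal + additional diagnosis per claim), and a disease table
(extra codes per claim number). The generative direction is
exposure → jaundice: per episode, exposure indicators are drawn (optionally
with a logit-linear income gradient), then the jaundice label from

logit P(jaundice) = α + Σ log(OR_k)·X_k + β_cesarean·I(cesarean) + β_income·(income group − 3),

with α calibrated by root finding so the realized jaundice fraction matches
the configured base rate. Conception is latent; only the first pregnancy
claim (uniform 28–84 d after conception) is observable — exactly the
censoring the pipeline faces in real data.

Defaults state the world the simulation studies run in: ~30,000 episodes
(25,000 women, 20 % with a second episode), gestation Normal(280, 10) d
truncated to [200, 308], cesarean fraction 0.38 (the control-group rate in
the reference demographics), jaundice base rate 1.3 % (mother-attached
coding captures only a small fraction of clinical jaundice, which is why
the reference cohort sits near 0.4–0.5 %; 1.3 % yields ≈ 400 cases at this
size, the scale the stability studies need), one income-confounded exposure
with true OR 3 at 3 % prevalence plus a null exposure at 10 %, income
gradients of 0.4 (exposure logit per income group) and 0.25 (jaundice logit
per group — consistent in magnitude with the income imbalance visible in
the reference demographics), and background noise diagnoses at 0.6 visits
per 30 d from a 30-code pool.

What the generator does *not* emulate: real code dictionaries (noise codes
are X00–X29 shaped like categories, not clinical entities), visit-level
correlation (noise is Poisson), income drift over years (fixed per woman by
default), and newborn-side records (the real data has none attached to the
mother either). A green parameter-recovery test therefore establishes that
the pipeline recovers planted effects under honest confounding and
censoring — not that it would reproduce any particular clinical finding.

Exclusion injections (stillbirth codes, missing qualification years,
pregnancy-codes-only windows) are off by default — the clean world in which
planted episodes and recovered cases are in exact bijection, which the suite
asserts — and are switched on by tests that check the exclusion ledger
arithmetic.

## Numerical and degenerate-input choices

* Zero row/column margins make the exact test undefined: error, not NA.
* `a = 0` gives OR 0 with CI (0, finite); `c = 0` with `a > 0` gives OR ∞
  with CI (finite, ∞); both flow through aggregation (∞ never averaged).
* Newton iterations cap at 100 with step halving; coefficients beyond ±15
  are flagged non-finite (separation); a singular information matrix stops
  iteration and reports non-estimable terms as NA.
* Conditional-likelihood invariance to covariate shifts is exploited for
  stability (columns are centered) and asserted as a test.
* All randomness flows from one master seed: per-repetition shuffle seeds
  are drawn once (`sample.int(2^31 - 1, n_reps)`), so any repetition can be
  replayed independently and a rerun is byte-identical.
* Monte-Carlo p-values use the (1 + hits)/(B + 1) estimator.

## Known limitations

* The exact-test p in the 3rd decimal can differ across two-sided
  conventions; the OR/CI are the stable quantities, and the minimum-
  likelihood rule is fixed here.
* Greedy matching is not optimal matching; with 1:10 and a large control
  pool the difference is negligible, but the spec'd algorithm is greedy and
  the package implements exactly that.
* `fisher_rxc_mc` is an estimate; for decisions at the 0.005 boundary use
  more than the default 10^4 draws.
* The pipeline tabulates only codes with ≥ 1 exposed case; all-zero rows
  carry no information and would make the output unbounded over the
  dictionary.
* Episode construction sees only mother-attached codes; neonatal outcomes
  not billed to the mother are invisible, a property inherited from the
  data model, not a bug.
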