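---
title: "Methods: nested case-control safety analysis of prescription claims"
author: "nccclaims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested case-control safety analysis of prescription claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nccclaims)
```

## The problem

Adverse drug reactions are rarely recorded as such in insurance-claims
databases, so safety studies built on claims must infer events from what the
database does record: prescriptions. `nccclaims` implements a nested
case-control design for one common situation — an index drug (here a widely
used injectable, co-administered with many other medications) suspected of
triggering acute allergic reactions. The surrogate signal of a reaction is a
prescription of an anti-allergic *marker drug* (an antihistamine, a
corticosteroid, calcium gluconate, or adrenaline) in a narrow window after
the index prescription. The exposure of interest is same-day co-prescription
of each of 25 target concomitant medications, and the estimand is the
matched odds ratio of a suspected reaction for users versus non-users of
each concomitant.

Because prescription dates carry no time of day, every temporal rule is
day-granular; dates are integer day indices and all window arithmetic is
integer subtraction.

## Case ascertainment

The cohort is every participant with at least one index-drug prescription;
the *index date* is the first of them, and the propensity covariates
(setting, hospital level) are read from that prescription row.

A marker prescription only counts if it is *incident*: at least
`washout_days` (default 30, the day-granular reading of a one-month run-in)
of observed, marker-free time must precede it. Two readings of the washout
anchor are possible — marker-free time since observation start, or since the
previous marker — and the implementation enforces both: the incident marker
date $m$ must satisfy $m - \text{start} \ge w$ and no marker may fall in
$[m-w,\, m-1]$. Participants whose only markers fail the washout have no
incident marker and remain control-eligible, like never-marker members; the
run manifest still counts them separately so the attrition flowchart can
distinguish the two.

With $d$ the day offset from index date to incident marker, the
classification is total and six-valued:

| $d$ | classification | analysis role |
|---|---|---|
| no marker | `no_marker` | control pool |
| $d<0$ | `marker_before_xyp` | excluded |
| $d=0$, index drug not re-prescribed next day | `expanded_same_day` | case (sensitivity only) |
| $d=0$, index drug re-prescribed next day | `same_day_continued` | excluded |
| $1\le d\le 3$ | `primary` | case (both analyses) |
| $d>3$ | `marker_gt_3_days` | excluded |

The 0–3-day window reflects the clinical observation that these reactions
usually occur within about 24 hours of administration; the same-day rules
deal with the impossibility of ordering two prescriptions on one date. The
*expanded* (sensitivity) definition assumes that stopping the index drug the
day after a same-day marker indicates the marker treated a reaction to it.
"Stopped the next day" is operationalized as *no index-drug prescription
dated index+1*; later re-prescriptions are ignored. Classifications are
invariant under a constant shift of all dates, which the tests assert.

The control pool is the never-incident-marker cohort; members excluded for
timing reasons appear in neither arm. Whether the source design drew
controls this way or required year-long marker-freedom is not determinable
from a prescription stream alone; the never-incident-marker pool is the
implemented choice because it is the natural complement of the case
definition and keeps the cohort an exact partition (asserted on every run).

## Propensity-score matching

Case status is regressed on four covariates — age (continuous, years),
gender, visit setting (inpatient/outpatient) and hospital level (tertiary
reference, two indicators) — by maximum-likelihood logistic regression
(IRLS, deviance tolerance $10^{-12}$, at most 100 iterations; the final
score norm is stored). Perfect separation raises an error naming the
separating covariate instead of returning divergent coefficients.

Matching is greedy 1:1 nearest-neighbor without replacement: cases in
descending propensity score (ties by ascending participant id), each taking
the unused control with the smallest absolute score difference (ties by
ascending control id). Units are canonically sorted first, so input row
order never changes the result. Three conventions are configurable because
greedy matching is a family, not one algorithm: processing order
(descending score, the common form of the cited convention, or seeded
random), matching scale (probability by default; logit switchable), and an
optional caliper in SD-of-logit units (none by default, since the source
design specifies none). Greedy matching is deliberately not optimal
assignment; a test documents that its total distance is bounded below by
the exhaustive optimum on a small fixture.

Balance diagnostics report, per covariate, mean ± SD or n (%) in each arm
plus standardized mean differences (pooled-SD denominator for age,
proportion-based for categorical levels).

## Exposure coding and estimators

A participant is exposed to a target drug iff a prescription of it shares
their index date; for case arms the exposure date must also not be after the
first marker date, which is automatic under same-date coding and asserted.
Marker drugs are never exposures. Route, dose and frequency are out of
scope by design.

Four estimators are provided:

* **Crude OR** from the unmatched 2×2 table, $\mathrm{OR}=ad/bc$, Woolf
  interval $\exp(\ln\mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$, Wald
  two-sided p. Any zero cell leaves the estimate undefined — reported as an
  em dash — unless the Haldane–Anscombe +0.5 correction is opted in.
* **Discordant-pair OR** $n_{10}/n_{01}$ with the analogous log-scale
  interval and the exact McNemar p (doubled binomial$(n_{10}+n_{01},
  \tfrac12)$ tail, capped at 1).
* **Conditional logistic regression** for 1:1 pairs, maximizing
  $\prod_j \left[1+\exp(-\beta^\top(x^{case}_j - x^{ctrl}_j))\right]^{-1}$
  by Newton–Raphson on pair differences (gradient $\sum_j z_j(1-p_j)$,
  observed information $\sum_j z_j z_j^\top p_j(1-p_j)$), from $\beta=0$,
  with step-halving, converged when the largest absolute gradient component
  is below $10^{-8}$ within 200 iterations. Coefficients with no discordant
  pairs (unidentified) or one-sided discordance (infinite MLE,
  quasi-separation) raise errors naming the drugs; unconverged fits are
  never returned. For a single binary exposure the estimate equals
  $\ln(n_{10}/n_{01})$ exactly, which the tests check to $10^{-8}$, and the
  maximizer is cross-checked against an independent optimizer and a
  likelihood grid.
* **Backward selection**: fit all candidate drugs (pre-dropping degenerate
  ones, with reasons attached), repeatedly remove the single variable with
  the largest Wald p above $\alpha = 0.05$ (two-sided) and refit, until all
  remaining p ≤ α. Wald-based elimination with single removals is the
  common default for this procedure; final odds ratios are reported in
  descending order.

The univariate report includes *both* the crude and the discordant-pair
estimator. On real published tables of this design the printed univariate
values match the crude computation for most drugs but not all, and no single
estimator reproduces every row; rather than silently resolving that
ambiguity the package reports both and leaves the choice explicit
(`univariate` flag).

The concomitant-count analysis tabulates the per-arm distribution of the
number of target drugs used and the crude OR of ≥1 versus 0. Subgroup
analyses stratify pairs by the case member's age band (<18, 18–64, ≥65) or
gender and re-run the same machinery per stratum; drugs with fewer than
`min_discordant` (default 5) discordant pairs in a stratum are reported as
insufficient rather than estimated. No multiple-testing adjustment is
applied anywhere, matching the reporting convention of this design; reports
should say so.

Report rounding is two decimals for ORs and intervals, with undefined
entries as em dashes.

## The synthetic generator

Because the motivating data source is restricted, the package ships a
seeded generator whose defaults encode the study conditions the pipeline is
meant to face:

* **Age** is a three-component mixture — child (uniform 0–18), adult
  (18–65), elderly (65–90) with weights 0.42/0.38/0.20 — populating the
  three analysis bands with the pediatric-heavy mix typical of this drug;
  gender is 53% male, 76% inpatient, hospital levels 26/52/22%.
* **Co-prescription** of each target drug on the index date follows a
  logistic model: baseline prevalences default to a 25-drug profile
  spanning ~0.3 down to ~0.003, mirroring the qualitative frequency
  ordering of such panels; optional covariate effects (age per decade,
  gender, setting, hospital level) induce confounding through exactly the
  covariates the propensity model uses, making the matching step's bias
  reduction empirically checkable.
* **Reaction status** is drawn once per participant (single index episode)
  from $\text{logit}(p) = \beta_0 + \sum_d \beta_d x_d$ with
  $\beta_0 = \text{qlogis}(0.10)$ by default — a calibration choice, since
  no incidence for the surrogate event is established; it yields
  marker-positive fractions comparable to claims cohorts of this kind.
* **Marker timing**: an allergic participant's marker is offset 0–3 days
  from the index date with default probabilities (0.35, 0.35, 0.20, 0.10) —
  most reactions within 24 h. `same_day_marker_fraction`, when set,
  overrides the offset-0 mass and rescales the rest; the distribution is
  otherwise authoritative. After a same-day marker the index drug continues
  next day with probability 0.5, exercising the same-day exclusion.
* **Background markers** arrive at 0.001/day throughout the window
  (≈26% of participants per year), including before the index date and more
  than 3 days after it, so every exclusion branch and the washout fire on
  realistic data.

All randomness flows from one seeded stream that neither reads nor disturbs
the global RNG state; identical configs and seeds give byte-identical
claims files.

What the generator does *not* emulate: real marginal drug frequencies
beyond qualitative ordering, repeat index-drug episodes, seasonality,
within-participant correlation of co-prescriptions, coding noise in drug
names, or informative censoring. Passing tests therefore demonstrate that
the pipeline recovers known effects under its own assumptions — not that
those assumptions hold in any particular claims database.

A second, pair-level generator (`simulate_matched_pairs()`) draws two
exposure vectors per pair and labels the case with probability
$e^{\beta^\top x_1}/(e^{\beta^\top x_1}+e^{\beta^\top x_2})$ — exactly the
1:1 conditional likelihood — so planted log odds ratios are the true
estimands of the conditional model. It isolates estimator behavior from the
cohort machinery and powers the parameter-recovery checks.

## Validation problem sizes

The shipped tests exercise, among others: parameter recovery of planted
odds ratios (4.0, 2.8, 1.5) on 2,000 pairs across 100 seeds (medians
required within ±20% of truth); the type-I error of the univariate test
over 500 replicates of the full matched pipeline on a null scenario of
2,600 participants with co-prescription prevalences 0.12–0.30 (false-positive
rate required inside the 95% binomial band around 5%; the moderate
prevalences are chosen so 2×2 cell counts are large enough for the Wald
test to be near-nominal, which is what a calibration check should measure);
end-to-end recovery of a planted OR 4 through simulate → ascertain → match →
estimate over 12 seeds of 2,500 participants; and exhaustive-enumeration
oracles for the greedy matcher on 3×5 fixtures.

## Known limitations

* Surrogate ascertainment misclassifies: background marker use within the
  0–3-day window creates false cases, and reactions treated without marker
  drugs are missed. The washout and the conservative same-day exclusions
  reduce, but cannot eliminate, this.
* The washout anchor and the control-eligibility window are conventions
  (documented above), not reconstructions of any specific study's rules.
* Greedy matching is order-dependent by construction; the defaults make it
  deterministic, not optimal.
* Exposure is same-day co-prescription only; duration, dose and route are
  ignored.
* One marker drug is itself a corticosteroid co-prescribed therapeutically
  with some of the target drugs in real practice, which can confound the
  surrogate; the generator's background rate mimics the noise but not that
  specific dependence.
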