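# nccclaims

Nested case-control drug-safety analysis of prescription-claims data.

`nccclaims` is for pharmacoepidemiologists who need to estimate whether
medications co-prescribed with an index drug change the risk of an acute
adverse reaction, when the only available signal of the reaction is itself a
prescription — an anti-allergic *marker drug* (antihistamine,
corticosteroid, calcium gluconate, adrenaline) dispensed shortly after the
index drug. The package implements the whole design as a reproducible
pipeline:

1. **Case ascertainment.** Cohort = all index-drug users, indexed at their
   first prescription. A case is a cohort member whose first *incident*
   marker prescription (≥ 30 observed marker-free days before it) falls 1–3
   days after the index date; an expanded (sensitivity) definition also
   admits same-day markers when the index drug is not re-prescribed the next
   day. Members with markers at other offsets are excluded from both arms;
   never-marker members form the control pool.
2. **Propensity-score matching.** Logistic model of case status on age,
   gender, visit setting and hospital level; deterministic greedy 1:1
   nearest-neighbor matching without replacement.
3. **Estimation.** For each of 25 target concomitants, exposure = same-day
   co-prescription with the index drug. Estimators: crude 2×2 odds ratio
   (Woolf interval), matched discordant-pair OR
   (OR = n₁₀/n₀₁, exact McNemar p), multivariable conditional logistic
   regression for 1:1 pairs (Newton–Raphson on pair differences) with
   backward Wald selection at α = 0.05, the ≥1-vs-0 concomitant-count
   contrast, and age-band/gender subgroup analyses.
4. **Synthetic ground truth.** A seeded claims generator plants known log
   odds ratios and confounding so the whole pipeline is testable end to
   end, plus a pair-level generator that samples directly from the
   conditional-likelihood model for estimator checks.

The core statistic is the 1:1 matched conditional likelihood

```
L(β) = ∏_j 1 / (1 + exp(−β′(x_case_j − x_control_j)))
```

whose maximizer for a single binary exposure is exactly ln(n₁₀/n₀₁); the
implementation verifies this identity, agreement with an independent
optimizer, and parameter recovery on simulated cohorts.

See `vignettes/nccclaims-methods.Rmd` for the model, conventions and
limitations in detail.

## Worked example

Simulate a 2,500-participant cohort in which gentamicin co-prescription
quadruples the odds of a reaction (true OR = 4), then run the full primary
analysis:

```r
library(nccclaims)
prev <- default_prevalence(); prev["gentamicin"] <- 0.15
res <- run_pipeline(list(
  scenario = list(n_participants = 2500,
                  true_log_or = list(gentamicin = log(4)),
                  coprescription_prevalence = as.list(prev)),
  seed = 20, outdir = "results/demo"))
cat(render_flowchart(res$manifest))
```

```
Study cohort (index-drug users): 2500
  Excluded, no anti-allergic marker prescription: 1469 (58.8% of cohort)
  Excluded, marker user without incident (washout-passing) marker: 48 (1.9% of cohort)
  Incident cases (washout-passing first marker): 983 (39.3% of cohort)
    Excluded, marker before / same-day-continued / >3 days after index: 789 (31.6% of cohort)
    Final cases: 194 (19.7% of incident cases)
      Matched pairs: 194 (100.0% of final cases)
```

```r
res$multivariable[, c("drug", "or", "ci_low", "ci_high", "p_value")]
```

```
        drug    or ci_low ci_high  p_value
1 gentamicin 5.674  2.884  11.162 4.94e-07
2    heparin 4.060  1.332  12.372 1.37e-02
3  lidocaine 0.223  0.056   0.892 3.38e-02
```

The planted gentamicin effect is recovered (OR 5.67, CI 2.88–11.16, truth
4); the heparin and lidocaine rows are the kind of chance selections
backward elimination at α = 0.05 produces when screening 25 null drugs in
194 pairs — the package applies no multiplicity correction, matching the
design's usual reporting, and the vignette discusses why single-run
selections must be read with that in mind. Across many seeds the median
recovered OR concentrates near truth (see the parameter-recovery tests).
`results/demo/` also receives `univariate.csv`, `counts.csv`,
`subgroups.csv`, `pairs.csv`, `cases.csv`, `balance.csv`, `manifest.json`
and `flowchart.txt`.

A thin CLI over the same functions ships in `inst/cli/nccclaims.R`
(`run`, `simulate`, `ascertain` subcommands).

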