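---
title: "Methods: the likely-responder reanalysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the likely-responder reanalysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likelyresponder)
```

## The problem

Randomized trials of alcohol-use-disorder pharmacotherapy often end null
on average while subsets of participants respond strongly: divergent
subgroup effects can cancel in the population mean.  The
likely-responder paradigm re-analyses such a two-arm trial by
(i) predicting every subject's response to *active* treatment from
baseline features alone, (ii) declaring subjects whose predicted
improvement clears a clinically motivated threshold to be likely
responders (LRs), and (iii) testing causal superiority of active
treatment over placebo within that predicted-responsive subgroup, with
the whole-sample test gated behind it.

The primary outcome is ΔHDD: the count of heavy drinking days (HDD) in
the 28-day baseline window minus the count in the final 4-week
maintenance window.  Positive values are improvement; the scale is
bounded, ΔHDD ∈ [−28, 28].

## The model, stage by stage

**Counterfactual response prediction.**  A regression random forest
(CART trees, variance-reduction splits, bootstrap resampling) is fit on
active-arm subjects only, giving Pred[ΔHDD | active, f] for a baseline
feature vector f.  Applied to placebo subjects the prediction is
counterfactual — what the model expects had they received active
treatment.  Out-of-bag (OOB) predictions are retained for every training
subject; the headline fit statistic is the Pearson correlation r between
observed and OOB-predicted ΔHDD and the implied percent of variance
explained, 100·r².  The forest is implemented in the package (compiled
code) because no random-forest package is assumed available; it
reproduces scikit-learn's `RandomForestRegressor` OOB and test behaviour
on matched benchmarks.

**Likely responders.**  LR ⇔ predicted ΔHDD ≥ τ with τ = 14 days by
default.  Because baseline HDD is at most 28, a reduction of at least 14
days is necessarily a reduction of at least 50% of baseline — the common
"50% responder" convention (`guaranteed_percent_reduction()`).  The
bound is closed: a score of exactly 14.0 is LR.

**Prognostic-score subclassification.**  The same prediction is used as
a prognostic balancing score: subjects are rank-ordered by score and cut
into contiguous quantile strata (2 for the LR subgroup, 5 for the whole
sample; sizes differ by at most one, remainder to the highest-score
blocks, ties broken by subject id).  Within a stratum the randomized
arms have approximately the same prognosis distribution, which
`balance_check()` quantifies with per-stratum Kolmogorov–Smirnov
statistics.

**Stratified estimation and closed testing.**  Within each analysis set
ΔHDD is regressed by OLS on a stratum factor, stratum-specific treatment
contrasts and a shared centered baseline-HDD slope; each
`stratum k : treat` coefficient is directly the treatment difference in
stratum k, with Wald t inference on residual degrees of freedom.  The
pooled effect is a weighted combination of stratum contrasts
(sample-size weights by default; equal weights available — the exact
pooling rule behind the motivating report's pooled row is not
recoverable, so both are exposed).  Two primary hypotheses are tested by
closed testing at α = 0.05: H1 (no effect among LRs) first; only if H1
is rejected is H2 (no effect in the whole sample) tested.  All other
p-values in the report tables are unadjusted and descriptive.

**Secondary outcomes.**  End-of-study measures are compared over the
four arm-by-responder cells with a cell-means model and exactly four
pooled-variance contrasts: active vs placebo within UR and within LR,
and UR vs LR within each arm.  Baseline LR-vs-UR comparisons use
Wilcoxon rank-sum tests (continuous/ordinal) or chi-square tests
(binary/categorical, no continuity correction by default).

**Perturbation risk differences.**  For a feature x and increment δ
(+1 unit by default), the forest is evaluated at f and at f with
x → clip(x + δ, bounds); the median across subjects of the prediction
change estimates the shift in expected active-treatment response per
unit of x.  The median, not the mean, is the headline because the
change distribution is typically skewed (the mean is logged alongside).
Confidence intervals come from a subject-level bootstrap of the median
(1000 resamples).  A report-level screen (|median| ≥ 0.4 days) marks
notable features without altering any estimate.  Two-feature joint
perturbations measure additivity: the interaction gap is
median(joint) − median(x₁) − median(x₂).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| responder threshold τ | 14 | days | ≥50% of the maximal 28-day baseline |
| LR / full strata | 2 / 5 | — | sample-size-dependent quantile counts |
| forest trees | 1000 | — | stable OOB estimates at n ≈ 170 |
| mtry | ⌊p/3⌋ | features | regression-forest convention |
| min leaf | 5 | subjects | regression-forest convention |
| imputation | PMM, 5 donors, 10 cycles | — | bounded, scale-respecting draws |
| α | 0.05 | — | family-wise level of the closed test |
| pooling | by sample size | — | see above; `equal` exposed |
| bootstrap | 1000 | resamples | percentile CI of the median |

## The synthetic world

No subject-level data from the motivating trial are available, so the
package ships a generator (`simulate_trial()`) whose *defaults are the
stated world* of the analysis:

* **Features.**  Demographics plus seven psychometric scales scored at
  item level (impulsivity 1–4, anxiety 0–3, depression 0–3, mood 0–4,
  craving 1–7, consequences 0–4, withdrawal 0–4), drawn from a Gaussian
  copula with within-block correlation 0.4–0.5 and discretized to their
  bounds.
* **Baseline severity.**  Baseline HDD is 4 + beta-binomial(24), mean
  ≈ 21.5 and support [4, 28] — the inclusion criterion of at least one
  heavy drinking day per week.
* **Prognosis and effect.**  h(f) = 5.5 + 0.30·baseline HDD − 1.0·(mood
  item − 2) gives a placebo-arm mean ΔHDD near 12 days;
  g(f) loads sparsely on single items (+2.0/unit impulsivity item,
  +1.4 consequences item, −1.2 and −0.9 mood/anxiety items, −0.8
  depression item, +0.20 per baseline-HDD day), the magnitude scale a
  per-feature perturbation analysis reports and a forest can recover at
  n ≈ 170.  The intercept is calibrated once by large-n Monte Carlo so
  41.7% of subjects have h + g ≥ 14 (the LR fraction 141/338); it is
  never revisited.
* **Noise.**  Additive Gaussian noise with SD 8 days.  This was derived
  from the motivating report's printed within-stratum standard errors
  (per-subject SD ≈ 9 including residual signal) and fixed before any
  test was run.
* **Counts and truncation.**  Potential outcomes are rounded and the
  outcome HDD count clipped to [0, 28] — truncation is applied to the
  count, not to ΔHDD, respecting the bounded count nature of the
  outcome.  Truncation slightly attenuates observed contrasts relative
  to the untruncated effect; invariance checks that require exactness
  therefore either use the untruncated oracle potentials or
  configurations where truncation is negligible.
* **Missingness.**  Missing-at-random, driven by fully observed
  demographics (age): ~1% of scale items and ~17% of entire outcome
  windows (58/338 in the motivating trial).  No MNAR mechanisms.

What the generator does **not** emulate: the real trial's joint feature
distribution, visit-level drinking dynamics, dropout processes, site
effects, or informative missingness.  A green test therefore
establishes that the *procedure* behaves as specified in a world with
the assumed statistical structure — not that the original trial's
numbers are reproduced.  Data-dependent results of the motivating
report (its specific means, p-values and risk differences) are out of
scope by design.

## Numerical and design choices

* **OOB scoring is the pipeline default.**  The motivating description
  applies the fitted forest to all subjects, which for the training arm
  means in-sample predictions.  Implementation showed this inflates the
  closed test's family-wise error severely (≈40% false rejection of H1
  in null-effect worlds at n = 150–338): a training subject's own
  outcome noise enters their score, so thresholding at τ selects active
  subjects with positive noise.  Scoring the training arm by its
  out-of-bag predictions removes the self-selection and restores the
  nominal 5% error (verified by simulation); `"full_forest"` remains
  available for fidelity to the original wording.
* **Missing outcome windows are imputed.**  Scattered missing drinking
  days count as heavy days in the primary outcome (the conservative
  worst-case rule); subjects missing their *entire* final window have
  the outcome imputed by predictive mean matching within the
  chained-equations pass, with treatment arm and baseline HDD always in
  the outcome model.  The all-heavy route for whole windows is
  selectable but drags arm means far below the levels the analysis
  model expects and injects baseline−28 outliers into the training
  outcome.
* **Chained equations.**  Visit order is ascending missingness; each
  conditional model is least squares with a tiny ridge (1e−6 of the
  mean diagonal) so collinear predictors cannot abort a cycle; PMM
  donors are the 5 observed values with closest predictions,
  deterministic tie-break by index.  One completed dataset (m = 1) is
  carried forward by default — the pipeline applies no pooling rules,
  and m > 1 returns a list to be analysed per-imputation.  The outcome
  and treatment arm are excluded from the baseline-feature models by
  default (flags to include) to avoid leakage.
* **FWER simulation design.**  The acceptance check of the closed
  test's family-wise error uses the generator's oracle prognostic score
  h(f) as the stratification score.  Under the global null any score
  that is a function of baseline data alone yields valid within-stratum
  randomization inference, and it keeps 2000 replicates inside a few
  minutes where refitting a 1000-tree forest per replicate could not;
  the leakage hazard of outcome-dependent scores is tested separately.
* **Determinism.**  Every stochastic stage takes a seed; the pipeline
  derives per-stage sub-seeds from one master seed, and a rerun is
  byte-identical.  The forest seeds each tree independently from
  (seed, tree index), so results do not depend on platform RNG state.
* **Degenerate inputs.**  Zero-variance predictions make r undefined
  (error); a stratum with an empty arm is an estimation error naming
  the cell; a single stratum degrades gracefully to the
  covariate-adjusted two-sample comparison; groups of n < 2 in the
  monthly summary are flagged with undefined CIs.

## Known limitations

* At the motivating trial's scale (n = 338, ~170 per arm) and the
  stated noise level, the forest's out-of-bag correlation fluctuates
  widely across worlds (≈0–0.2); many simulated trials are honestly
  inconclusive, and responder-label agreement with the oracle is ~0.65
  at n = 1000.  This is a property of the signal-to-noise regime, not
  of the implementation (benchmarked against scikit-learn).
* The quantile placement of the motivating report's alternating stratum
  sizes (68, 67, 68, 67, 68) is not reproducible by any standard
  remainder rule; only the attained size multiset {67, 68} is treated
  as normative.
* No Rubin's-rules pooling across imputations, no MNAR sensitivity
  analysis, no robust standard errors by default, and no attempt to
  reproduce data-dependent numbers from the motivating report.
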