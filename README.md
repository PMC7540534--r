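# likelyresponder

Causal "likely responder" reanalysis of a two-arm randomized clinical
trial, for biostatisticians re-examining trials that ended null on
average but plausibly hide responsive subgroups — the motivating
setting is alcohol-use-disorder pharmacotherapy with the heavy-drinking
-day count as outcome.

## The method

Let Y(1), Y(0) be a subject's potential ΔHDD outcomes (baseline heavy
drinking days minus final-4-week heavy drinking days; positive =
improvement) under active treatment and placebo, and f their baseline
features.  The pipeline:

1. fits a regression random forest for **Pred[ΔHDD | active, f]** on
   active-arm subjects only, and scores *every* subject — factually for
   the active arm (out-of-bag by default), counterfactually for placebo;
2. classifies **likely responders (LR)** by predicted ΔHDD ≥ 14 days
   (on a 28-day scale this guarantees a ≥ 50% reduction from baseline);
3. treats the prediction as a **prognostic balancing score**,
   rank-orders it into contiguous quantile strata (2 for LRs, 5 for the
   full sample), and fits OLS
   `ΔHDD ~ stratum + stratum:treatment + centered baseline HDD`,
   so each interaction coefficient is the within-stratum causal
   contrast; stratum contrasts are pooled by sample size;
4. tests the two primary hypotheses by **closed testing** at α = 0.05 —
   H1 (no effect among LRs) gates H2 (no effect overall) — controlling
   the family-wise error rate;
5. reports baseline LR-vs-UR comparisons, four-contrast secondary
   outcome tables, and per-feature **risk differences**: the median
   change in predicted ΔHDD caused by a one-unit increment of a single
   baseline item, with bootstrap CIs.

A synthetic-trial generator with oracle access to every subject's true
effect (block-correlated psychometric items, feature-dependent
treatment effect, MAR missingness) stands in for the unavailable trial
data and backs all calibration and validation.

## Worked example

```r
library(likelyresponder)
cfg <- pipeline_config(input = simulation_config(n_subjects = 1000),
                       seed = 42)
res <- run_pipeline(cfg, quiet = TRUE)
print(res)
#> likely-responder pipeline result
#> trial_dataset: 1000 subjects (498 active, 502 placebo), 47 features, 28-day outcome window
#> OOB fit: r = 0.167 (95% CI 0.081, 0.251), variance explained = 2.80%, n = 498
#> likely responders: 197 of 1000
#> pooled effect: 2.27 days (95% CI 0.48, 4.06), p = 0.01304
#> pooled effect: 0.94 days (95% CI 0.06, 1.81), p = 0.03583
#> closed test (alpha = 0.05): H1 (likely responders) p = 0.01304 -> reject; H2 (full sample) p = 0.03583 -> reject
```

Reading the output: the forest explains 2.8% of outcome variance
out-of-bag (this world is noisy: outcome SD ≈ 9 days against a
prognostic spread of ≈ 4).  197 of 1000 subjects are predicted to
improve by ≥ 14 days.  Among them, active treatment beats placebo by an
estimated 2.27 days of ΔHDD (p = 0.013), so the gate opens and the
full-sample hypothesis is tested, where the average effect is a modest
0.94 days.  The full-sample stratum table shows the signature pattern —
benefit concentrated in the top prognostic quintile (+2.33 days,
p = 0.019), nothing in the middle:

```r
res$effects_full[, c("stratum", "estimate", "ci_low", "ci_high", "p")]
#>   stratum estimate ci_low ci_high     p
#> 1       1     1.16  -0.81     3.1 0.247
#> 2       2     0.68  -1.28     2.6 0.496
#> 3       3     0.11  -1.84     2.1 0.915
#> 4       4     0.41  -1.53     2.4 0.678
#> 5       5     2.33   0.38     4.3 0.019
```

The top of the risk-difference table recovers exactly the items that
drive this world's true effect and prognosis (a mood item, a
consequences item, an impulsivity item, an anxiety item):

```r
head(res$table5[order(-abs(res$table5$median_change)),
                c("feature", "median_change", "ci_low", "ci_high")], 5)
#>    feature median_change ci_low ci_high
#> 30 poms_q6         -0.26  -0.28   -0.24
#> 39  imb_q3          0.25   0.22    0.27
#> 6   bis_q2          0.24   0.20    0.27
#> 26 poms_q2         -0.17  -0.19   -0.15
#> 14  bai_q2         -0.16  -0.17   -0.15
```

With `outdir` set, `run_pipeline()` writes the full report bundle
(baseline table, LR and full-sample effect tables, outcome contrasts,
risk differences, QQ pairs, monthly HDD trajectories, closed-test
verdict, run manifest) as CSV/JSON.  A command-line front end lives in
`inst/cli/lr-pipeline` (subcommands `simulate`, `impute`, `fit`,
`score`, `stratify`, `test`, `run-all`).

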