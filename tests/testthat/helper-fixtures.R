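# Fixtures are built in code; nothing is read from disk.

# A complete (no-missingness) synthetic trial, outcome already derived.
complete_trial <- function(n = 200, seed = 1, ...) {
  simulate_trial(simulation_config(n_subjects = n, seed = seed,
                                   missing_rate_items = 0,
                                   missing_rate_outcome = 0, ...))
}

# Minimal hand-built dataset: one continuous feature x plus delta_hdd set
# directly; used for exact OLS recovery oracles.
crafted_dataset <- function(delta_hdd, arm, baseline_hdd = NULL,
                            x = NULL) {
  n <- length(delta_hdd)
  if (is.null(baseline_hdd)) baseline_hdd <- rep(20L, n)
  if (is.null(x)) x <- seq_len(n)
  sch <- feature_schema(name = "x", kind = "continuous")
  d <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), arm = arm,
                  baseline_hdd = baseline_hdd,
                  outcome_hdd = clip(baseline_hdd - delta_hdd, 0, 28),
                  delta_hdd = delta_hdd, x = x, stringsAsFactors = FALSE)
  trial_dataset(d, sch)
}

# Regression-oracle dataset: features are plain numeric columns with wide
# continuous bounds, outcome delta_hdd = f(features) + noise (clipped into
# the feasible range so trial invariants hold).
oracle_regression_trial <- function(X, y, arm = NULL) {
  n <- nrow(X)
  if (is.null(arm)) arm <- rep("active", n)
  sch <- feature_schema(name = colnames(X), kind = "continuous",
                        min = -Inf, max = Inf)
  sch$min <- NA_real_
  sch$max <- NA_real_
  delta <- clip(round(y, 6), -28, 28)
  bhdd <- rep(28L, n)
  d <- cbind(data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                        arm = arm, baseline_hdd = bhdd,
                        outcome_hdd = clip(bhdd - delta, 0, 28),
                        delta_hdd = delta, stringsAsFactors = FALSE),
             as.data.frame(X))
  trial_dataset(d, sch)
}
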