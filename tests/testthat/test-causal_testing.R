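# crafted noise-free strata: k strata x 2 arms with chosen effects
crafted_strata <- function(effects, n_per_cell = 10, slope = 0.5) {
  k <- length(effects)
  n <- 2 * k * n_per_cell
  stratum <- rep(seq_len(k), each = 2 * n_per_cell)
  arm <- rep(rep(c("active", "placebo"), each = n_per_cell), k)
  bhdd <- rep(rep(c(18L, 20L, 22L, 24L), length.out = n_per_cell), 2 * k)
  base_mean <- 5 + 2 * stratum
  delta <- base_mean + slope * (bhdd - mean(bhdd)) +
    ifelse(arm == "active", effects[stratum], 0)
  ds <- crafted_dataset(delta_hdd = delta, arm = arm, baseline_hdd = bhdd)
  asg <- data.frame(subject_id = ds$data$subject_id, arm = arm,
                    score = stratum + seq_len(n) / (10 * n),
                    stratum = stratum, stringsAsFactors = FALSE)
  list(ds = ds, asg = asg)
}

test_that("stratified OLS recovers injected effects exactly without noise", {
  effects <- c(-4, 0, 2.5, 4, 7)
  cs <- crafted_strata(effects)
  fit <- fit_stratified_model(cs$ds, cs$asg)
  est <- stratum_effects(fit)
  expect_equal(est$estimate, effects, tolerance = 1e-9)
  expect_equal(est$n_active, rep(10, 5))
  # constant effect: every stratum contrast equals it exactly
  cs2 <- crafted_strata(rep(3, 4))
  est2 <- stratum_effects(fit_stratified_model(cs2$ds, cs2$asg))
  expect_equal(est2$estimate, rep(3, 4), tolerance = 1e-9)
})

test_that("pooled effect combines stratum contrasts as weighted means", {
  # equal effects: pooled equals them under either weighting
  cs <- crafted_strata(rep(3, 4))
  fit <- fit_stratified_model(cs$ds, cs$asg)
  expect_equal(pooled_effect(fit, "by_n")$estimate, 3, tolerance = 1e-9)
  expect_equal(pooled_effect(fit, "equal")$estimate, 3, tolerance = 1e-9)

  # (-4, 0, +4) with equal n cancel under equal weights
  cs2 <- crafted_strata(c(-4, 0, 4))
  fit2 <- fit_stratified_model(cs2$ds, cs2$asg)
  expect_equal(pooled_effect(fit2, "equal")$estimate, 0, tolerance = 1e-9)

  # unbalanced strata: by_n vs equal differ by the analytic gap
  effects <- c(2, 6)
  cs3 <- crafted_strata(effects, n_per_cell = 8)
  # drop half of stratum 2 to unbalance (keep both arms)
  keep <- !(cs3$asg$stratum == 2 &
              seq_len(nrow(cs3$asg)) %in% c(17:20, 25:28))
  ds3 <- cs3$ds; ds3$data <- ds3$data[keep, ]
  asg3 <- cs3$asg[keep, ]
  fit3 <- fit_stratified_model(ds3, asg3)
  est3 <- stratum_effects(fit3)$estimate
  n_strat <- as.vector(table(asg3$stratum))
  gap_expected <- sum(est3 * n_strat / sum(n_strat)) - mean(est3)
  gap <- pooled_effect(fit3, "by_n")$estimate -
    pooled_effect(fit3, "equal")$estimate
  expect_equal(gap, gap_expected, tolerance = 1e-9)
})

test_that("a single stratum reduces to the covariate-adjusted comparison", {
  sim <- complete_trial(n = 300, seed = 44)
  ds <- sim$dataset
  sc <- data.frame(subject_id = ds$data$subject_id, arm = ds$data$arm,
                   score = 1, stringsAsFactors = FALSE)
  asg <- partition_quantiles(sc, 1)
  fit <- fit_stratified_model(ds, asg)
  pooled <- pooled_effect(fit)
  # oracle: plain lm of delta on treatment + centered baseline
  df <- data.frame(y = ds$data$delta_hdd,
                   tr = as.numeric(ds$data$arm == "active"),
                   b = ds$data$baseline_hdd - mean(ds$data$baseline_hdd))
  ref <- stats::lm(y ~ tr + b, data = df)
  expect_equal(pooled$estimate, unname(coef(ref)["tr"]), tolerance = 1e-9)
  expect_equal(pooled$p,
               summary(ref)$coefficients["tr", "Pr(>|t|)"],
               tolerance = 1e-9)

  # and with no covariate it is the raw difference in arm means
  fit0 <- fit_stratified_model(ds, asg, adjust_baseline = FALSE)
  raw <- mean(df$y[df$tr == 1]) - mean(df$y[df$tr == 0])
  expect_equal(pooled_effect(fit0)$estimate, raw, tolerance = 1e-9)
})

test_that("empty arm-stratum cells are rejected with the cell named", {
  cs <- crafted_strata(c(1, 2))
  drop <- cs$asg$stratum == 2 & cs$asg$arm == "placebo"
  ds <- cs$ds; ds$data <- ds$data[!drop, ]
  expect_error(fit_stratified_model(ds, cs$asg[!drop, ]),
               "stratum 2 has no placebo")
})

test_that("p-values are uniform under a permuted-label global null", {
  set.seed(50)
  reps <- 300
  pvals <- vapply(seq_len(reps), function(i) {
    n <- 120
    y <- rnorm(n, 10, 4)
    arm <- sample(rep(c("active", "placebo"), n / 2))
    ds <- crafted_dataset(delta_hdd = round(y, 3), arm = arm,
                          baseline_hdd = sample(12:28, n, replace = TRUE))
    sc <- data.frame(subject_id = ds$data$subject_id, arm = arm,
                     score = rnorm(n), stringsAsFactors = FALSE)
    fit <- fit_stratified_model(ds, partition_quantiles(sc, 3))
    pooled_effect(fit)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  rej <- mean(pvals <= 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("closed testing gates the full-sample hypothesis", {
  # the two pooled p-values printed for the motivating reanalysis
  ct <- closed_test(0.031, 0.704, 0.05)
  expect_equal(ct$h1, "reject")
  expect_equal(ct$h2, "retain")

  ct2 <- closed_test(0.20, 0.001, 0.05)
  expect_equal(ct2$h1, "retain")
  expect_equal(ct2$h2, "not_tested")

  ct3 <- closed_test(0.01, 0.02, 0.05)
  expect_equal(ct3$h2, "reject")
  expect_error(closed_test(1.2, 0.5), "p_lr")
})

test_that("model fit statistics square the observed-fitted correlation", {
  expect_equal(round(percent_variance_explained(0.53), 2), 28.09)
  expect_equal(round(percent_variance_explained(0.52), 2), 27.04)
  cs <- crafted_strata(c(2, 4, 6))
  fit <- fit_stratified_model(cs$ds, cs$asg)
  mfs <- model_fit_stats(fit)
  expect_equal(mfs$pct_variance, 100 * mfs$r^2, tolerance = 1e-9)
  expect_equal(mfs$pct_variance, 100, tolerance = 1e-6)  # saturated, noise-free
})

test_that("stratum CIs attain nominal coverage under noise", {
  set.seed(61)
  reps <- 150
  cover4 <- logical(reps)
  cover0 <- logical(reps)
  for (i in seq_len(reps)) {
    cs <- crafted_strata(c(4, 0), n_per_cell = 40)
    noisy <- cs$ds
    noisy$data$delta_hdd <- round(noisy$data$delta_hdd + rnorm(160, 0, 3), 4)
    noisy$data$outcome_hdd <- clip(noisy$data$baseline_hdd -
                                     noisy$data$delta_hdd, 0, 28)
    est <- stratum_effects(fit_stratified_model(noisy, cs$asg))
    cover4[i] <- est$ci_low[1] <= 4 && est$ci_high[1] >= 4
    cover0[i] <- est$ci_low[2] <= 0 && est$ci_high[2] >= 0
  }
  se <- sqrt(0.95 * 0.05 / reps)
  expect_gt(mean(cover4), 0.95 - 4 * se)
  expect_gt(mean(cover0), 0.95 - 4 * se)
})
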