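test_that("perturbation specs validate their inputs", {
  expect_error(perturbation_spec("x", 0), "nonzero")
  sim <- complete_trial(n = 120, seed = 80)
  m <- fit_treated_model(sim$dataset, forest_config(n_trees = 20, seed = 1))
  expect_error(perturb_predict(m, sim$dataset, perturbation_spec("race")),
               "categorical")
  expect_error(perturb_predict(m, sim$dataset, perturbation_spec("nope")),
               "unknown feature")
})

test_that("an irrelevant feature induces exactly zero change", {
  # deterministic target on one feature: trees become pure after
  # splitting on it, so the noise feature never appears in any split
  set.seed(81)
  n <- 400
  X <- cbind(x = sample(1:4, n, replace = TRUE), z = rnorm(n))
  ds <- oracle_regression_trial(X, 3 * X[, "x"])
  m <- fit_treated_model(ds, forest_config(n_trees = 100, mtry = 2,
                                           seed = 2))
  ch <- perturb_predict(m, ds, perturbation_spec("z"))
  expect_true(all(ch == 0))
  # while the driving feature moves predictions upward
  ch2 <- perturb_predict(m, ds, perturbation_spec("x"))
  expect_gt(median(ch2), 1)
})

test_that("clipping keeps perturbed values within declared bounds", {
  sim <- complete_trial(n = 150, seed = 82)
  ds <- sim$dataset
  m <- fit_treated_model(ds, forest_config(n_trees = 20, seed = 3))
  # push an ordinal item past its top: subjects already at the bound get 0
  at_max <- ds$data$bai_q4 == 3
  expect_gt(sum(at_max), 0)
  ch <- perturb_predict(m, ds, perturbation_spec("bai_q4", 1))
  expect_true(all(ch[at_max] == 0))
  ch_ex <- perturb_predict(m, ds, perturbation_spec("bai_q4", 1),
                           exclude_clipped = TRUE)
  expect_equal(length(ch_ex), sum(!at_max))
})

test_that("a linear oracle is recovered by the median unit change", {
  set.seed(83)
  n <- 2000
  X <- cbind(x = runif(n, 0, 10), z1 = rnorm(n), z2 = rnorm(n),
             z3 = rnorm(n))
  y <- 2 * X[, "x"] + rnorm(n, 0, 1)
  ds <- oracle_regression_trial(X, y)
  m <- fit_treated_model(ds, forest_config(n_trees = 300, mtry = 2,
                                           seed = 4))
  ch <- perturb_predict(m, ds, perturbation_spec("x", 1))
  expect_lt(abs(median(ch) - 2), 0.4)  # within 20% of the true slope
})

test_that("summarize_risk degenerates and reproduces known sampling", {
  rd <- summarize_risk(rep(1.5, 50), n_boot = 100, seed = 1)
  expect_equal(rd$median, 1.5)
  expect_equal(rd$ci95, c(1.5, 1.5))

  set.seed(84)
  ch <- rnorm(338, 1.37, 0.5)
  rd2 <- summarize_risk(ch, n_boot = 500, seed = 2)
  boot_se <- (rd2$ci95[2] - rd2$ci95[1]) / (2 * 1.96)
  expect_lt(abs(rd2$median - 1.37), 3 * boot_se)
  # reproducible under a fixed seed
  expect_identical(rd2$ci95, summarize_risk(ch, n_boot = 500, seed = 2)$ci95)

  # skewness rationale: for a right-skewed change distribution the
  # median sits below the mean
  skew <- rexp(500, 1)
  rd3 <- summarize_risk(skew, n_boot = 100, seed = 3)
  expect_lt(rd3$median, rd3$mean)
})

test_that("median change is invariant to subject order", {
  sim <- complete_trial(n = 150, seed = 85)
  ds <- sim$dataset
  m <- fit_treated_model(ds, forest_config(n_trees = 30, seed = 5))
  ch <- perturb_predict(m, ds, perturbation_spec("poms_q2", 1))
  perm <- ds
  set.seed(1)
  perm$data <- perm$data[sample(nrow(perm$data)), ]
  ch_perm <- perturb_predict(m, perm, perturbation_spec("poms_q2", 1))
  expect_equal(median(ch), median(ch_perm))
})

test_that("pairwise additivity separates additive from interactive oracles", {
  set.seed(86)
  n <- 2000
  X <- cbind(x1 = runif(n, 0, 6), x2 = runif(n, 0, 6), z = rnorm(n))
  ds_add <- oracle_regression_trial(X, 2 * X[, "x1"] + 3 * X[, "x2"] +
                                      rnorm(n, 0, 0.5))
  m_add <- fit_treated_model(ds_add, forest_config(n_trees = 200, mtry = 2,
                                                   seed = 6))
  gap_add <- pairwise_additivity(m_add, ds_add, perturbation_spec("x1", 1),
                                 perturbation_spec("x2", 1),
                                 n_boot = 200, seed = 1)
  expect_lt(abs(gap_add$gap), 0.5)

  ds_mul <- oracle_regression_trial(X, X[, "x1"] * X[, "x2"] +
                                      rnorm(n, 0, 0.5))
  m_mul <- fit_treated_model(ds_mul, forest_config(n_trees = 200, mtry = 2,
                                                   seed = 7))
  gap_mul <- pairwise_additivity(m_mul, ds_mul, perturbation_spec("x1", 1),
                                 perturbation_spec("x2", 1),
                                 n_boot = 200, seed = 2)
  expect_gt(abs(gap_mul$gap), 0.3)

  expect_error(pairwise_additivity(m_add, ds_add,
                                   perturbation_spec("x1", 1),
                                   perturbation_spec("x1", 1)),
               "same feature")
})

test_that("monotone targets give sign-coherent median changes", {
  set.seed(87)
  for (s in 1:5) {
    n <- 800
    X <- cbind(x = runif(n, 0, 8), z = rnorm(n))
    y <- 1.5 * X[, "x"] + rnorm(n, 0, 2)
    ds <- oracle_regression_trial(X, y)
    m <- fit_treated_model(ds, forest_config(n_trees = 150, mtry = 1,
                                             seed = s))
    ch <- perturb_predict(m, ds, perturbation_spec("x", 1))
    expect_gte(median(ch), 0)
  }
})

test_that("the risk-difference table screens on magnitude only", {
  sim <- complete_trial(n = 300, seed = 88)
  ds <- sim$dataset
  m <- fit_treated_model(ds, forest_config(n_trees = 150, seed = 8))
  tab <- risk_difference_table(m, ds,
                               features = c("bis_q2", "poms_q2", "ciwa_q1"),
                               n_boot = 100, seed = 9)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$passes_screen, abs(tab$median_change) >= 0.4)
  expect_true(all(tab$ci_low <= tab$median_change &
                    tab$median_change <= tab$ci_high))
})
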