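test_that("a noise-free single-feature target is learned almost exactly", {
  # delta is an exact function of one ordinal feature; with all features
  # available at each split the OOB fit must be near-perfect
  set.seed(22)
  n <- 1000
  X <- cbind(x = sample(1:4, n, replace = TRUE), z1 = rnorm(n),
             z2 = rnorm(n))
  ds <- oracle_regression_trial(X, 3 * X[, "x"])
  m <- fit_treated_model(ds, forest_config(n_trees = 300, mtry = 3,
                                           seed = 1))
  expect_gte(fit_diagnostics(m)$r, 0.9)
})

test_that("a feature-independent outcome yields near-zero OOB r-squared", {
  prog <- function(features, baseline_hdd) rep(10, nrow(features))
  sim <- simulate_trial(simulation_config(n_subjects = 2000, seed = 23,
                                          effect = "null", noise_sd = 8,
                                          prognosis = prog,
                                          missing_rate_items = 0,
                                          missing_rate_outcome = 0))
  m <- fit_treated_model(sim$dataset, forest_config(n_trees = 300, seed = 2))
  expect_lt(fit_diagnostics(m)$r_squared_pct, 2)
})

test_that("the forest is deterministic given its seed", {
  sim <- complete_trial(n = 200, seed = 24)
  m1 <- fit_treated_model(sim$dataset, forest_config(n_trees = 50, seed = 5))
  m2 <- fit_treated_model(sim$dataset, forest_config(n_trees = 50, seed = 5))
  expect_identical(predict(m1, sim$dataset), predict(m2, sim$dataset))
  expect_identical(m1$oob, m2$oob)
  m3 <- fit_treated_model(sim$dataset, forest_config(n_trees = 50, seed = 6))
  expect_false(identical(predict(m1, sim$dataset), predict(m3, sim$dataset)))
})

test_that("scores recover the oracle expected-response ranking", {
  sim <- complete_trial(n = 2000, seed = 25)
  m <- fit_treated_model(sim$dataset, forest_config(n_trees = 500, seed = 3))
  sc <- score_all(m, sim$dataset)
  hg <- sim$oracle$h + sim$oracle$g
  expect_gte(cor(sc$score, hg, method = "spearman"), 0.5)

  sim2 <- complete_trial(n = 1000, seed = 26)
  m2 <- fit_treated_model(sim2$dataset, forest_config(n_trees = 500, seed = 3))
  sc2 <- score_all(m2, sim2$dataset)
  expect_gte(cor(sc2$score, sim2$oracle$h + sim2$oracle$g,
                 method = "spearman"), 0.35)
})

test_that("scores are invariant to row order and to placebo outcomes", {
  sim <- complete_trial(n = 150, seed = 27)
  ds <- sim$dataset
  m <- fit_treated_model(ds, forest_config(n_trees = 60, seed = 4))
  sc <- score_all(m, ds)

  perm <- ds
  set.seed(1)
  perm$data <- perm$data[sample(nrow(perm$data)), ]
  sc_perm <- score_all(m, perm)
  idx <- match(sc$subject_id, sc_perm$subject_id)
  expect_identical(sc$score, sc_perm$score[idx])

  # altering a placebo subject's observed outcome cannot move its score
  alt <- ds
  pl <- which(alt$data$arm == "placebo")[1]
  alt$data$outcome_hdd[pl] <- 0
  alt$data$delta_hdd[pl] <- alt$data$baseline_hdd[pl]
  expect_identical(score_all(m, alt)$score[pl], sc$score[pl])

  expect_true(all(sc$counterfactual == (sc$arm == "placebo")))
})

test_that("identical feature vectors produce identical scores", {
  sch <- feature_schema(c("x1", "x2"), "continuous")
  n <- 60
  set.seed(2)
  d <- data.frame(subject_id = sprintf("S%02d", 1:n),
                  arm = rep(c("active", "placebo"), n / 2),
                  baseline_hdd = 20L,
                  outcome_hdd = sample(0:20, n, replace = TRUE),
                  x1 = 1, x2 = 2, stringsAsFactors = FALSE)
  d$delta_hdd <- d$baseline_hdd - d$outcome_hdd
  ds <- trial_dataset(d, sch)
  m <- fit_treated_model(ds, forest_config(n_trees = 40, seed = 1),
                         min_n = 10)
  sc <- score_all(m, ds)
  expect_equal(length(unique(sc$score)), 1)
})

test_that("in-sample fit dominates out-of-bag fit", {
  sim <- complete_trial(n = 500, seed = 28)
  ds <- sim$dataset
  m <- fit_treated_model(ds, forest_config(n_trees = 300, seed = 7))
  act <- ds$data$arm == "active"
  full_r <- cor(predict(m, ds)[act], ds$data$delta_hdd[act])
  expect_gte(full_r, fit_diagnostics(m)$r)
})

test_that("fit diagnostics reproduce the printed correlation arithmetic", {
  expect_equal(round(percent_variance_explained(0.415), 2), 17.22)
  expect_equal(percent_variance_explained(1), 100)
  expect_equal(percent_variance_explained(-1), 100)
  expect_error(percent_variance_explained(1.2), "-1, 1")

  # Fisher-z interval at the printed n and r (frozen oracle values)
  ci <- likelyresponder:::fisher_z_ci(0.415, 170)
  expect_equal(ci, c(0.2821071, 0.5322670), tolerance = 1e-6)
  # close to the printed interval (0.30, 0.52), method unstated there
  expect_lt(max(abs(ci - c(0.30, 0.52))), 0.025)
})

test_that("fit errors are informative", {
  sim <- simulate_trial(simulation_config(n_subjects = 150, seed = 29,
                                          missing_rate_items = 0.05,
                                          missing_rate_outcome = 0))
  expect_error(fit_treated_model(sim$dataset, forest_config(n_trees = 10)),
               "impute_chained")
  small <- complete_trial(n = 40, seed = 30)
  expect_error(fit_treated_model(small$dataset,
                                 forest_config(n_trees = 10)),
               "active arm")
  # schema mismatch on scoring
  ok <- complete_trial(n = 120, seed = 31)
  m <- fit_treated_model(ok$dataset, forest_config(n_trees = 10, seed = 1))
  other <- crafted_dataset(delta_hdd = rep(1, 10),
                           arm = rep(c("active", "placebo"), 5))
  expect_error(score_all(m, other), "schema mismatch")
})

test_that("oob mode substitutes out-of-bag scores for training subjects", {
  sim <- complete_trial(n = 200, seed = 32)
  ds <- sim$dataset
  m <- fit_treated_model(ds, forest_config(n_trees = 100, seed = 8))
  sc_full <- score_all(m, ds)
  sc_oob <- score_all(m, ds, mode = "oob")
  act <- ds$data$arm == "active"
  expect_true(all(sc_oob$provenance[act] == "oob"))
  expect_true(all(sc_oob$provenance[!act] == "full_forest"))
  expect_identical(sc_full$score[!act], sc_oob$score[!act])
  expect_false(identical(sc_full$score[act], sc_oob$score[act]))
})
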