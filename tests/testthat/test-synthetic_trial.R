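test_that("identical config and seed reproduce the trial bit-identically", {
  a <- simulate_trial(simulation_config(n_subjects = 120, seed = 9))
  b <- simulate_trial(simulation_config(n_subjects = 120, seed = 9))
  expect_identical(a$dataset$data, b$dataset$data)
  expect_identical(a$oracle, b$oracle)
  c <- simulate_trial(simulation_config(n_subjects = 120, seed = 10))
  expect_false(identical(a$dataset$data, c$dataset$data))
})

test_that("null effect with zero noise equalizes the potential outcomes", {
  sim <- simulate_trial(simulation_config(n_subjects = 150, effect = "null",
                                          noise_sd = 0,
                                          missing_rate_items = 0,
                                          missing_rate_outcome = 0,
                                          seed = 3))
  expect_equal(sim$oracle$y_active, sim$oracle$y_placebo)
  expect_equal(sim$oracle$g, rep(0, 150))
})

test_that("observed outcome equals the assigned arm's potential outcome", {
  sim <- complete_trial(n = 300, seed = 5)
  d <- sim$dataset$data
  expected <- ifelse(d$arm == "active", sim$oracle$y_active,
                     sim$oracle$y_placebo)
  expect_equal(d$delta_hdd, expected)
})

test_that("arm counts stay within exact binomial bounds", {
  n_active <- vapply(1:20, function(s) {
    sim <- simulate_trial(simulation_config(seed = s,
                                            missing_rate_items = 0,
                                            missing_rate_outcome = 0))
    sum(sim$dataset$data$arm == "active")
  }, numeric(1))
  # each draw within extreme exact-binomial quantiles, and the aggregate
  # within 4 SE of the binomial mean (individual 3-sigma excursions are
  # expected over repeated seeds)
  expect_true(all(n_active >= qbinom(1e-6, 338, 0.5) &
                    n_active <= qbinom(1 - 1e-6, 338, 0.5)))
  z <- (sum(n_active) - 20 * 169) / sqrt(20 * 338 * 0.25)
  expect_lt(abs(z), 4)
})

test_that("generated values satisfy all trial invariants", {
  sim <- simulate_trial(simulation_config(n_subjects = 250, seed = 12))
  d <- sim$dataset$data
  expect_silent(validate_trial(sim$dataset))
  expect_true(all(d$baseline_hdd >= 4 & d$baseline_hdd <= 28))
  expect_true(all(d$outcome_hdd >= 0 & d$outcome_hdd <= 28))
  expect_true(all(abs(d$delta_hdd) <= 28))
  # MAR rates near nominal
  sch <- sim$dataset$schema
  items <- sch$name[grepl("_q\\d+$", sch$name)]
  frac_items <- mean(is.na(as.matrix(d[, items])))
  expect_lt(abs(frac_items - 0.01), 0.01)
  frac_window <- mean(grepl("^M+$", d$outcome_days))
  expect_lt(abs(frac_window - 0.17), 0.08)
})

test_that("constant effect is recovered as the arm difference at n = 10000", {
  # configured so outcome truncation at the count bounds is negligible
  # (truncation attenuates the observed contrast; see methods vignette)
  sim <- simulate_trial(simulation_config(
    n_subjects = 10000, effect = "constant", effect_constant = 4,
    prognosis = function(features, baseline_hdd) 0.5 * (baseline_hdd - 10),
    noise_sd = 1, missing_rate_items = 0, missing_rate_outcome = 0,
    seed = 21))
  d <- sim$dataset$data
  diff <- mean(d$delta_hdd[d$arm == "active"]) -
    mean(d$delta_hdd[d$arm == "placebo"])
  se <- sqrt(var(d$delta_hdd[d$arm == "active"]) / sum(d$arm == "active") +
               var(d$delta_hdd[d$arm == "placebo"]) / sum(d$arm == "placebo"))
  expect_lt(abs(diff - 4), 3 * se)
  # and exactly on the untruncated oracle potentials under the default
  # heterogeneous world
  sim2 <- complete_trial(n = 5000, seed = 22)
  raw_diff <- sim2$oracle$y_active_raw - sim2$oracle$y_placebo_raw
  expect_equal(mean(raw_diff - sim2$oracle$g), 0, tolerance = 0.3)
})

test_that("single-item threshold effect matches its analytic expectation", {
  # g(f) = 14 * 1[bis_q2 >= 3]; bis_q2 = 1 + Binomial(3, 0.55), so
  # P(effect) = P(B >= 2) and E[g] = 14 * P, computed analytically
  eff <- function(features, baseline_hdd) 14 * (features$bis_q2 >= 3)
  sim <- simulate_trial(simulation_config(n_subjects = 20000, effect = eff,
                                          missing_rate_items = 0,
                                          missing_rate_outcome = 0,
                                          seed = 31))
  p_hit <- pbinom(1, 3, 0.55, lower.tail = FALSE)
  expected <- 14 * p_hit
  mc_se <- 14 * sqrt(p_hit * (1 - p_hit) / 20000)
  expect_lt(abs(mean(sim$oracle$g) - expected), 3 * mc_se)
  # labels recompute exactly from the oracle
  lab <- true_subgroup_labels(sim$oracle, 14)
  expect_identical(unname(lab),
                   sim$oracle$h + sim$oracle$g >= 14)
})

test_that("true_subgroup_labels handles extreme thresholds", {
  sim <- complete_trial(n = 80, seed = 2)
  expect_true(all(true_subgroup_labels(sim$oracle, -Inf)))
  expect_false(any(true_subgroup_labels(sim$oracle, 29)))
})

test_that("infeasible configs and invalid parameters are rejected", {
  expect_error(simulation_config(allocation = 1))
  expect_error(simulation_config(noise_sd = -1))
  expect_error(simulate_trial(simulation_config(n_subjects = 100,
                                                effect = "constant",
                                                effect_constant = 1000,
                                                noise_sd = 0, seed = 1,
                                                missing_rate_items = 0,
                                                missing_rate_outcome = 0)),
               "infeasible")
})
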