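# Stratified estimation and closed testing of the causal treatment
# difference.  Within quantile strata of the prognostic score, ΔHDD is
# regressed on a stratum factor, stratum-specific treatment contrasts and
# a shared centered baseline-HDD slope; the pooled effect is a weighted
# combination of the stratum contrasts.  Two primary hypotheses (no
# effect among likely responders; no effect in the whole sample) are
# tested by closed testing: the whole-sample hypothesis is examined only
# if the likely-responder hypothesis is rejected, controlling the
# family-wise error rate at alpha.

#' Fit the stratified treatment-effect model
#'
#' Ordinary least squares of ΔHDD on treatment assignment, centered
#' baseline HDD, stratum, and treatment-by-stratum interactions,
#' parameterized so each `stratum k : treat` coefficient is directly the
#' treatment difference (active − placebo) in stratum k.
#'
#' @param dataset a `trial_dataset` with `delta_hdd` present.
#' @param assignment a [partition_quantiles()] result covering a subset of
#'   the dataset's subjects (e.g. the LR subgroup or the full sample).
#' @param adjust_baseline include the centered baseline-HDD covariate
#'   (default TRUE, per the primary analysis model).
#' @return a `stratified_fit` object.
#' @export
fit_stratified_model <- function(dataset, assignment,
                                 adjust_baseline = TRUE) {
  d <- dataset$data
  idx <- match(assignment$subject_id, d$subject_id)
  if (anyNA(idx)) {
    stop_validation("assignment contains subjects absent from the dataset")
  }
  df <- data.frame(delta_hdd = d$delta_hdd[idx],
                   treat = as.numeric(d$arm[idx] == "active"),
                   bhdd = d$baseline_hdd[idx],
                   stratum = factor(assignment$stratum))
  if (anyNA(df$delta_hdd)) {
    stop_validation("missing delta_hdd in analysis set; derive or impute ",
                    "outcomes first")
  }
  cell <- table(df$stratum, df$treat)
  if (any(cell == 0)) {
    empty <- which(cell == 0, arr.ind = TRUE)[1, ]
    stop_validation("stratum ", rownames(cell)[empty[1]], " has no ",
                    c("placebo", "active")[empty[2]],
                    " subjects; design singular")
  }
  df$bhdd_c <- df$bhdd - mean(df$bhdd)
  # with one stratum the factor is degenerate; drop to the plain
  # covariate-adjusted two-sample model
  fml <- if (nlevels(df$stratum) == 1) {
    if (adjust_baseline) delta_hdd ~ treat + bhdd_c else delta_hdd ~ treat
  } else if (adjust_baseline) {
    delta_hdd ~ 0 + stratum + stratum:treat + bhdd_c
  } else {
    delta_hdd ~ 0 + stratum + stratum:treat
  }
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    stop_validation("rank-deficient design (aliased coefficient: ",
                    names(stats::coef(fit))[is.na(stats::coef(fit))][1], ")")
  }
  k <- nlevels(df$stratum)
  n_arm <- table(stratum = df$stratum, arm = ifelse(df$treat == 1,
                                                    "active", "placebo"))
  structure(list(lm = fit, k = k, data = df, n_arm = n_arm,
                 strata_levels = levels(df$stratum)),
            class = "stratified_fit")
}

#' @export
print.stratified_fit <- function(x, ...) {
  cat(sprintf("stratified_fit: %d strata, n = %d, residual df = %d\n",
              x$k, nrow(x$data), x$lm$df.residual))
  invisible(x)
}

contrast_estimate <- function(fit, w, scope) {
  cf <- stats::coef(fit$lm)
  V <- stats::vcov(fit$lm)
  est <- sum(w * cf)
  se <- sqrt(drop(t(w) %*% V %*% w))
  df <- fit$lm$df.residual
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- stats::qt(0.975, df)
  list(scope = scope, estimate = est, se = se,
       ci95 = c(est - q * se, est + q * se), p = p, df = df)
}

effect_weights <- function(fit, stratum) {
  cf_names <- names(stats::coef(fit$lm))
  w <- numeric(length(cf_names))
  names(w) <- cf_names
  nm <- paste0("stratum", stratum, ":treat")
  if (!nm %in% cf_names) nm <- "treat"  # single-stratum model
  if (!nm %in% cf_names) stop_validation("no treatment coefficient found")
  w[nm] <- 1
  w
}

#' Per-stratum treatment effect estimates
#'
#' The treatment difference (active − placebo, in ΔHDD days) in each
#' stratum, with Wald 95% confidence interval and two-sided t-test
#' p-value on residual degrees of freedom.  Unadjusted: per-stratum
#' p-values indicate effect size within the stratum and are not
#' multiplicity-controlled.
#'
#' @param fit a `stratified_fit`.
#' @return data frame with one row per stratum: estimate, CI, p, arm
#'   sizes and observed arm means.
#' @export
stratum_effects <- function(fit) {
  out <- do.call(rbind, lapply(fit$strata_levels, function(s) {
    ce <- contrast_estimate(fit, effect_weights(fit, s), paste0("stratum ", s))
    sub <- fit$data[fit$data$stratum == s, ]
    data.frame(stratum = s,
               n_active = sum(sub$treat == 1),
               n_placebo = sum(sub$treat == 0),
               mean_active = mean(sub$delta_hdd[sub$treat == 1]),
               mean_placebo = mean(sub$delta_hdd[sub$treat == 0]),
               estimate = ce$estimate, se = ce$se,
               ci_low = ce$ci95[1], ci_high = ce$ci95[2], p = ce$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled treatment effect across strata
#'
#' A weighted combination of the per-stratum treatment contrasts:
#' `"by_n"` (default) weights each stratum by its sample size, `"equal"`
#' weights strata equally.  Inference via the delta method (linear
#' contrast of OLS coefficients) with residual degrees of freedom.
#'
#' @param fit a `stratified_fit`.
#' @param weights `"by_n"` or `"equal"`.
#' @return an `effect_estimate` list: estimate, se, ci95, p, df, weights.
#' @export
pooled_effect <- function(fit, weights = c("by_n", "equal")) {
  weights <- match.arg(weights)
  n_strat <- table(fit$data$stratum)
  wts <- if (weights == "by_n") {
    as.numeric(n_strat) / sum(n_strat)
  } else {
    rep(1 / fit$k, fit$k)
  }
  w <- numeric(length(stats::coef(fit$lm)))
  names(w) <- names(stats::coef(fit$lm))
  if (fit$k == 1 && "treat" %in% names(w)) {
    w["treat"] <- 1
  } else {
    for (i in seq_along(fit$strata_levels)) {
      w[paste0("stratum", fit$strata_levels[i], ":treat")] <- wts[i]
    }
  }
  ce <- contrast_estimate(fit, w, "pooled")
  structure(c(ce, list(weights = weights, stratum_weights = wts)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s effect: %.2f days (95%% CI %.2f, %.2f), p = %.4g\n",
              x$scope, x$estimate, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Closed testing of the two primary hypotheses
#'
#' H1: no treatment difference among likely responders; H2: no treatment
#' difference in the whole sample.  H1 is tested at level alpha; if it is
#' not rejected, testing ends and H2 is not tested.  If H1 is rejected,
#' H2 is tested at alpha.  This gatekeeping controls the family-wise
#' error rate at alpha.
#'
#' @param p_lr p-value for the likely-responder pooled effect.
#' @param p_full p-value for the whole-sample pooled effect.
#' @param alpha family-wise level (default 0.05).
#' @return a `closed_test_result` list: alpha, p-values and decisions
#'   `h1` (`"reject"`/`"retain"`), `h2`
#'   (`"reject"`/`"retain"`/`"not_tested"`).
#' @export
closed_test <- function(p_lr, p_full, alpha = 0.05) {
  stopifnot(p_lr >= 0, p_lr <= 1, p_full >= 0, p_full <= 1,
            alpha > 0, alpha < 1)
  h1 <- if (p_lr <= alpha) "reject" else "retain"
  h2 <- if (h1 == "reject") {
    if (p_full <= alpha) "reject" else "retain"
  } else {
    "not_tested"
  }
  structure(list(alpha = alpha, p_lr = p_lr, p_full = p_full,
                 h1 = h1, h2 = h2),
            class = "closed_test_result")
}

#' @export
print.closed_test_result <- function(x, ...) {
  cat(sprintf("closed test (alpha = %g): H1 (likely responders) p = %.4g -> %s; H2 (full sample) p = %.4g -> %s\n",
              x$alpha, x$p_lr, x$h1, x$p_full, x$h2))
  invisible(x)
}

#' Goodness of fit of the stratified model
#'
#' Pearson correlation between observed ΔHDD and model-fitted values and
#' the implied percent of variance explained.
#'
#' @param fit a `stratified_fit`.
#' @return list: `r`, `pct_variance`.
#' @export
model_fit_stats <- function(fit) {
  fitted <- stats::fitted(fit$lm)
  if (stats::sd(fitted) == 0) {
    stop_validation("zero-variance fitted values; correlation undefined")
  }
  r <- stats::cor(fit$data$delta_hdd, fitted)
  list(r = r, pct_variance = percent_variance_explained(r))
}
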