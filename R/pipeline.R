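# End-to-end pipeline orchestration: impute -> fit -> score -> classify
# -> stratify -> test (likely responders, then the closed-test gate, then
# the full sample) -> group comparisons -> risk differences, with
# publication-shaped CSV/JSON outputs and a run manifest.

#' Pipeline configuration
#'
#' @param input either a `simulation_config` (the trial is generated) or
#'   a path to a trial CSV.
#' @param schema [feature_schema()]; required when `input` is a path,
#'   ignored for simulated input.
#' @param imputation an [imputation_config()]; its seed is overridden by
#'   a sub-seed of `seed`.
#' @param forest a [forest_config()]; seed likewise derived.
#' @param responder a [responder_config()].
#' @param score_mode active-arm scoring mode for classification:
#'   `"oob"` (default) scores training-arm subjects by their out-of-bag
#'   predictions so that no subject's own outcome enters their own
#'   responder label -- without this the stratified test's type-I error
#'   is badly inflated under the null; `"full_forest"` applies the full
#'   forest to everyone (the in-sample variant).
#' @param alpha family-wise level for the closed test (default 0.05).
#' @param pooling `"by_n"` or `"equal"` stratum weights.
#' @param n_boot bootstrap resamples for risk differences.
#' @param missing_outcome_rule how subjects with missing outcome-window
#'   days enter the primary outcome: `"impute"` (default; outcome HDD for
#'   incomplete windows is imputed by chained equations alongside the
#'   baseline items, the route consistent with imputing missing values on
#'   all variables) or `"all_heavy"` (missing days counted as heavy).
#' @param riskdiff_features features for the risk-difference table;
#'   `NULL` = all non-categorical features.
#' @param seed master seed; every stochastic stage draws a deterministic
#'   sub-seed from it.
#' @param outdir output directory (created if needed); `NULL` = no files
#'   written, results only returned.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = simulation_config(),
                            schema = NULL,
                            imputation = imputation_config(),
                            forest = forest_config(),
                            responder = responder_config(),
                            score_mode = c("oob", "full_forest"),
                            alpha = 0.05, pooling = "by_n",
                            n_boot = 1000L,
                            missing_outcome_rule = c("impute", "all_heavy"),
                            riskdiff_features = NULL,
                            seed = 1L, outdir = NULL) {
  missing_outcome_rule <- match.arg(missing_outcome_rule)
  score_mode <- match.arg(score_mode)
  structure(list(input = input, schema = schema, imputation = imputation,
                 forest = forest, responder = responder,
                 score_mode = score_mode, alpha = alpha, pooling = pooling,
                 n_boot = as.integer(n_boot),
                 missing_outcome_rule = missing_outcome_rule,
                 riskdiff_features = riskdiff_features,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE, optional = TRUE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Monthly mean HDD by responder group (active arm)
#'
#' Group mean and t-based 95% CI of the monthly HDD count per responder
#' group, for subjects randomized to active treatment: the trajectory
#' view of responder separation over the trial.
#'
#' @param dataset a `trial_dataset` with `hdd_month_*` columns.
#' @param labels a [classify_responders()] result.
#' @return data frame: month, label, n, mean, ci_low, ci_high (CI is `NA`
#'   and flagged for groups of n < 2).
#' @export
monthly_hdd_summary <- function(dataset, labels) {
  d <- dataset$data
  mcols <- grep("^hdd_month_", names(d), value = TRUE)
  if (!length(mcols)) {
    warning("no hdd_month_* columns present; monthly summary skipped")
    return(NULL)
  }
  mcols <- mcols[order(as.integer(sub("^hdd_month_", "", mcols)))]
  lab <- labels$label[match(d$subject_id, labels$subject_id)]
  act <- d$arm == "active"
  rows <- list()
  for (m in mcols) {
    for (gl in c("LR", "UR")) {
      v <- d[[m]][act & lab == gl & !is.na(d[[m]])]
      n <- length(v)
      if (n >= 2) {
        se <- stats::sd(v) / sqrt(n)
        q <- stats::qt(0.975, n - 1)
        ci <- mean(v) + c(-1, 1) * q * se
      } else {
        ci <- c(NA_real_, NA_real_)
      }
      rows[[length(rows) + 1]] <-
        data.frame(month = as.integer(sub("^hdd_month_", "", m)),
                   label = gl, n = n,
                   mean = if (n) mean(v) else NA_real_,
                   ci_low = ci[1], ci_high = ci[2],
                   degenerate = n < 2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full likely-responder pipeline
#'
#' Executes every stage from a single config, logging per-stage subject
#' counts, and (when `outdir` is set) writes the report bundle: baseline
#' comparison, LR and full-sample stratified effect tables, secondary
#' outcome contrasts, risk-difference table, QQ pairs, monthly HDD
#' summary, closed-test verdict and a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging (default FALSE).
#' @return a `pipeline_result` list with all intermediate and final
#'   objects.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  oracle <- NULL
  if (inherits(config$input, "simulation_config")) {
    sim_cfg <- config$input
    sim_cfg$seed <- sub_seed(config$seed, "simulate")
    sim <- run_stage("simulate", simulate_trial(sim_cfg))
    dataset <- sim$dataset
    oracle <- sim$oracle
    log_msg("simulate: %d subjects generated", nrow(dataset$data))
  } else {
    if (is.null(config$schema)) stop("schema required for CSV input")
    dataset <- run_stage("load", load_trial(config$input, config$schema))
    log_msg("load: %d subjects read", nrow(dataset$data))
  }

  derive_rule <- if (config$missing_outcome_rule == "impute") {
    "require_complete"
  } else {
    config$missing_outcome_rule
  }
  dataset <- run_stage("derive_outcome", derive_outcome(dataset, derive_rule))

  imp_cfg <- config$imputation
  imp_cfg$seed <- sub_seed(config$seed, "impute")
  if (config$missing_outcome_rule == "impute") imp_cfg$impute_outcome <- TRUE
  dataset <- run_stage("impute", impute_chained(dataset, imp_cfg))
  log_msg("impute: %d features complete", nrow(dataset$schema))

  f_cfg <- config$forest
  f_cfg$seed <- sub_seed(config$seed, "forest")
  model <- run_stage("fit", fit_treated_model(dataset, f_cfg))
  diagnostics <- run_stage("fit", fit_diagnostics(model))
  log_msg("fit: %d active-arm training subjects, OOB r = %.3f",
          length(model$train_ids), diagnostics$r)

  scores <- run_stage("score", score_all(model, dataset,
                                         mode = config$score_mode))
  labels <- run_stage("classify", classify_responders(scores,
                                                      config$responder))
  n_lr <- sum(labels$label == "LR")
  log_msg("classify: %d likely responders / %d subjects (%d active)",
          n_lr, nrow(labels), sum(labels$label == "LR" &
                                    labels$arm == "active"))

  lr_scores <- labels[labels$label == "LR", ]
  strata_lr <- run_stage("stratify",
                         partition_quantiles(lr_scores,
                                             config$responder$n_strata_lr))
  strata_full <- run_stage("stratify",
                           partition_quantiles(labels,
                                               config$responder$n_strata_full))
  balance_lr <- run_stage("stratify", balance_check(strata_lr,
                                                    warn_empty = FALSE))
  balance_full <- run_stage("stratify", balance_check(strata_full,
                                                      warn_empty = FALSE))

  fit_lr <- run_stage("test", fit_stratified_model(dataset, strata_lr))
  fit_full <- run_stage("test", fit_stratified_model(dataset, strata_full))
  eff_lr <- run_stage("test", stratum_effects(fit_lr))
  eff_full <- run_stage("test", stratum_effects(fit_full))
  pooled_lr <- run_stage("test", pooled_effect(fit_lr, config$pooling))
  pooled_full <- run_stage("test", pooled_effect(fit_full, config$pooling))
  verdict <- run_stage("test", closed_test(pooled_lr$p, pooled_full$p,
                                           config$alpha))
  log_msg("test: LR pooled %.2f (p = %.4g), full pooled %.2f (p = %.4g); H1 %s, H2 %s",
          pooled_lr$estimate, pooled_lr$p, pooled_full$estimate,
          pooled_full$p, verdict$h1, verdict$h2)

  table1 <- run_stage("compare", baseline_compare(dataset, labels))
  table4 <- run_stage("compare", outcome_contrasts(dataset, labels))
  monthly <- run_stage("compare", monthly_hdd_summary(dataset, labels))

  table5 <- run_stage("riskdiff",
                      risk_difference_table(model, dataset,
                                            features = config$riskdiff_features,
                                            n_boot = config$n_boot,
                                            seed = sub_seed(config$seed,
                                                            "riskdiff")))

  result <- structure(list(dataset = dataset, oracle = oracle,
                           model = model, diagnostics = diagnostics,
                           scores = scores, labels = labels,
                           strata_lr = strata_lr, strata_full = strata_full,
                           balance_lr = balance_lr,
                           balance_full = balance_full,
                           effects_lr = eff_lr, effects_full = eff_full,
                           pooled_lr = pooled_lr, pooled_full = pooled_full,
                           closed_test = verdict, table1 = table1,
                           table4 = table4, table5 = table5,
                           monthly_hdd = monthly, config = config),
                      class = "pipeline_result")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    write_trial(dataset, file.path(od, "trial_imputed.csv"))
    if (!is.null(oracle)) write_num_csv(oracle, file.path(od, "oracle.csv"))
    write_num_csv(scores, file.path(od, "scores.csv"))
    write_num_csv(labels, file.path(od, "labels.csv"))
    write_num_csv(as.data.frame(strata_lr), file.path(od, "strata_lr.csv"))
    write_num_csv(as.data.frame(strata_full),
                  file.path(od, "strata_full.csv"))
    write_num_csv(table1, file.path(od, "table1_baseline.csv"))
    effect_table <- function(eff, pooled) {
      rbind(eff,
            data.frame(stratum = "pooled", n_active = sum(eff$n_active),
                       n_placebo = sum(eff$n_placebo),
                       mean_active = NA_real_, mean_placebo = NA_real_,
                       estimate = pooled$estimate, se = pooled$se,
                       ci_low = pooled$ci95[1], ci_high = pooled$ci95[2],
                       p = pooled$p, stringsAsFactors = FALSE))
    }
    write_num_csv(effect_table(eff_lr, pooled_lr),
                  file.path(od, "table2_lr_effects.csv"))
    write_num_csv(effect_table(eff_full, pooled_full),
                  file.path(od, "table3_full_effects.csv"))
    write_num_csv(table4, file.path(od, "table4_outcomes.csv"))
    write_num_csv(table5, file.path(od, "table5_risk_differences.csv"))
    write_num_csv(diagnostics$qq_pairs, file.path(od, "qq_pairs.csv"))
    if (!is.null(monthly)) {
      write_num_csv(monthly, file.path(od, "monthly_hdd.csv"))
    }
    jsonlite::write_json(list(alpha = verdict$alpha, p_lr = verdict$p_lr,
                              p_full = verdict$p_full, h1 = verdict$h1,
                              h2 = verdict$h2),
                         file.path(od, "closed_test.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      seed = config$seed,
      stage_seeds = list(simulate = sub_seed(config$seed, "simulate"),
                         impute = sub_seed(config$seed, "impute"),
                         forest = sub_seed(config$seed, "forest"),
                         riskdiff = sub_seed(config$seed, "riskdiff")),
      n_subjects = nrow(dataset$data),
      n_active = sum(dataset$data$arm == "active"),
      n_likely_responders = n_lr,
      score_mode = config$score_mode, alpha = config$alpha,
      pooling = config$pooling,
      threshold = config$responder$threshold,
      n_trees = config$forest$n_trees,
      package_version = as.character(utils::packageVersion("likelyresponder")),
      r_version = paste(R.version$major, R.version$minor, sep = "."))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("likely-responder pipeline result\n")
  print(x$dataset)
  print(x$diagnostics)
  cat(sprintf("likely responders: %d of %d\n",
              sum(x$labels$label == "LR"), nrow(x$labels)))
  print(x$pooled_lr)
  print(x$pooled_full)
  print(x$closed_test)
  invisible(x)
}
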