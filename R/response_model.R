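# Counterfactual response predictor: a regression random forest fit on
# active-arm subjects only, scoring every subject's expected ΔHDD under
# active treatment.  For placebo-arm subjects the score is counterfactual.

#' Random forest configuration
#'
#' @param n_trees number of trees (default 1000).
#' @param mtry candidate features per split; `NULL` (default) uses the
#'   regression convention `floor(p/3)`, a value in (0,1) is read as a
#'   fraction of p.
#' @param min_leaf minimum terminal-node size (default 5).
#' @param seed integer seed; the forest is deterministic given the seed.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 1000L, mtry = NULL, min_leaf = 5L,
                          seed = 1L) {
  stopifnot(n_trees >= 1, min_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "forest_config")
}

# numeric model matrix for the forest: ordinal/binary/continuous features
# as-is, categorical features one-hot expanded (all levels; trees have no
# collinearity concerns)
build_model_matrix <- function(dataset) {
  sch <- dataset$schema
  d <- dataset$data
  cols <- lapply(seq_len(nrow(sch)), function(i) {
    nm <- sch$name[i]
    if (sch$kind[i] == "categorical") {
      lv <- schema_levels(sch, nm)
      m <- vapply(lv, function(l) as.numeric(d[[nm]] == l),
                  numeric(nrow(d)))
      colnames(m) <- paste0(nm, "=", lv)
      m
    } else {
      m <- matrix(as.numeric(d[[nm]]), ncol = 1)
      colnames(m) <- nm
      m
    }
  })
  do.call(cbind, cols)
}

#' Fit the treated-arm response model
#'
#' Trains a regression random forest for Pred\[ΔHDD | active, f\] on
#' active-arm subjects with an observed outcome, using baseline features
#' only.  Out-of-bag (OOB) predictions for every training subject are
#' retained for fit diagnostics.
#'
#' @param dataset an imputed `trial_dataset` (no missing features) with
#'   `delta_hdd` derived.
#' @param config a [forest_config()].
#' @param min_n minimum active-arm size (default 30); set lower only
#'   deliberately.
#' @return a `response_model` object.
#' @export
fit_treated_model <- function(dataset, config = forest_config(),
                              min_n = 30L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!"delta_hdd" %in% names(dataset$data)) {
    stop_validation("delta_hdd not derived; run derive_outcome() first")
  }
  X_all <- build_model_matrix(dataset)
  if (anyNA(X_all)) {
    bad <- colnames(X_all)[colSums(is.na(X_all)) > 0]
    stop_validation("missing feature values (", bad[1],
                    ", ...); run impute_chained() first")
  }
  train <- which(dataset$data$arm == "active" &
                   !is.na(dataset$data$delta_hdd))
  if (length(train) < min_n) {
    stop_validation("active arm with observed outcome has only ",
                    length(train), " subjects (< ", min_n, ")")
  }
  X <- X_all[train, , drop = FALSE]
  y <- dataset$data$delta_hdd[train]
  p <- ncol(X)
  mtry <- config$mtry
  if (is.null(mtry)) {
    mtry <- max(1L, p %/% 3L)
  } else if (mtry > 0 && mtry < 1) {
    mtry <- max(1L, as.integer(floor(mtry * p)))
  }
  mtry <- as.integer(mtry)
  if (mtry < 1 || mtry > p) stop_validation("mtry out of range [1, ", p, "]")
  fit <- .rf_fit_cpp(X, y, config$n_trees, mtry, config$min_leaf,
                     as.numeric(config$seed))
  structure(list(forest = fit$trees, config = config, mtry = mtry,
                 feature_names = colnames(X_all), schema = dataset$schema,
                 train_ids = dataset$data$subject_id[train],
                 oob = as.numeric(fit$oob), observed = y),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("response_model: %d trees, mtry %d, %d features, %d active-arm training subjects\n",
              length(x$forest), x$mtry, length(x$feature_names),
              length(x$train_ids)))
  invisible(x)
}

#' @export
predict.response_model <- function(object, dataset, ...) {
  X <- build_model_matrix(dataset)
  if (!identical(colnames(X), object$feature_names)) {
    stop_validation("schema mismatch: unmatched features: ",
                    paste(setdiff(object$feature_names, colnames(X)),
                          collapse = ", "))
  }
  if (anyNA(X)) stop_validation("missing feature values; impute first")
  as.numeric(.rf_predict_cpp(object$forest, X))
}

#' Score every subject's predicted response to active treatment
#'
#' Applies the treated-arm model to all subjects regardless of arm or
#' observed outcome.  Placebo-arm scores are counterfactual full-forest
#' predictions.  For active-arm subjects, `mode = "full_forest"` (default)
#' uses the full forest; `mode = "oob"` substitutes out-of-bag predictions
#' for training subjects, the leakage-averse alternative.
#'
#' @param model a `response_model`.
#' @param dataset a schema-compatible `trial_dataset`.
#' @param mode `"full_forest"` or `"oob"`.
#' @return data frame: `subject_id`, `arm`, `score` (predicted ΔHDD,
#'   days), `provenance` (`"full_forest"`/`"oob"`), `counterfactual`
#'   (TRUE iff placebo arm).
#' @export
score_all <- function(model, dataset, mode = c("full_forest", "oob")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "response_model"))
  score <- predict(model, dataset)
  prov <- rep("full_forest", nrow(dataset$data))
  if (mode == "oob") {
    idx <- match(model$train_ids, dataset$data$subject_id)
    ok <- !is.na(idx) & !is.na(model$oob)
    score[idx[ok]] <- model$oob[ok]
    prov[idx[ok]] <- "oob"
  }
  data.frame(subject_id = dataset$data$subject_id, arm = dataset$data$arm,
             score = score, provenance = prov,
             counterfactual = dataset$data$arm == "placebo",
             stringsAsFactors = FALSE)
}

#' Percent of variance explained from a correlation
#'
#' The model's goodness of fit is summarised as the square of the
#' correlation between observed and predicted outcomes, expressed in
#' percent: `100 * r^2`.
#'
#' @param r Pearson correlation in \[-1, 1\].
#' @return percent of variance explained.
#' @export
percent_variance_explained <- function(r) {
  if (any(is.na(r)) || any(abs(r) > 1)) {
    stop_validation("correlation must lie in [-1, 1]")
  }
  100 * r^2
}

fisher_z_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Out-of-bag fit diagnostics of the response model
#'
#' Pearson correlation between observed and OOB-predicted ΔHDD on the
#' training (active) arm, the implied percent of variance explained, a
#' Fisher-z 95% confidence interval for the correlation, and paired
#' sorted quantiles of observed vs predicted values (QQ pairs).
#'
#' @param model a fitted `response_model`.
#' @return a `fit_diagnostics` list: `r`, `r_squared_pct`, `ci95`, `n`,
#'   `qq_pairs` (data frame `observed`, `predicted`).
#' @export
fit_diagnostics <- function(model) {
  stopifnot(inherits(model, "response_model"))
  ok <- !is.na(model$oob)
  obs <- model$observed[ok]
  pred <- model$oob[ok]
  if (stats::sd(pred) == 0) {
    stop_validation("degenerate OOB predictions (zero variance); r undefined")
  }
  r <- stats::cor(obs, pred)
  structure(list(r = r, r_squared_pct = percent_variance_explained(r),
                 ci95 = fisher_z_ci(r, length(obs)), n = length(obs),
                 qq_pairs = data.frame(observed = sort(obs),
                                       predicted = sort(pred))),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("OOB fit: r = %.3f (95%% CI %.3f, %.3f), variance explained = %.2f%%, n = %d\n",
              x$r, x$ci95[1], x$ci95[2], x$r_squared_pct, x$n))
  invisible(x)
}
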