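# Chained-equations imputation of missing baseline items (fully
# conditional specification).  Each incomplete feature is regressed on all
# other features in turn; missing cells are refilled from the fitted
# conditional model, and the cycle is iterated.  Predictive mean matching
# (PMM) is the default draw for every feature kind: the imputed value is
# the observed value of a donor whose model prediction is close, which
# keeps ordinal/binary imputations on their scale automatically.

#' Imputation configuration
#'
#' @param n_iterations chained-equation cycles (default 10).
#' @param n_imputations number of completed datasets m (default 1; the
#'   pipeline carries a single completed dataset forward).
#' @param method `"pmm"` (predictive mean matching, default) or `"norm"`
#'   (linear prediction plus Gaussian residual draw; ordinal/binary values
#'   are rounded and clipped to their declared bounds).
#' @param donors number of PMM donor candidates (default 5).
#' @param include_arm should treatment arm enter the imputation model?
#'   Default `FALSE`.
#' @param include_outcome should the outcome enter the imputation model
#'   for baseline features?  Default `FALSE` (avoids outcome leakage into
#'   baseline features).
#' @param impute_outcome impute missing `outcome_hdd` (and hence
#'   `delta_hdd`) by predictive mean matching after the feature cycles?
#'   Default `FALSE`.  The outcome model always includes treatment arm
#'   and baseline HDD in addition to the completed features, since the
#'   outcome distribution differs by arm.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @return an `imputation_config` list.
#' @export
imputation_config <- function(n_iterations = 10L, n_imputations = 1L,
                              method = c("pmm", "norm"), donors = 5L,
                              include_arm = FALSE, include_outcome = FALSE,
                              impute_outcome = FALSE, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_iterations >= 1, n_imputations >= 1, donors >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_imputations = as.integer(n_imputations),
                 method = method, donors = as.integer(donors),
                 include_arm = include_arm,
                 include_outcome = include_outcome,
                 impute_outcome = impute_outcome,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# least squares with a small ridge so collinear predictors never abort a
# cycle; returns list(coef, sigma)
ridge_lm <- function(X, y) {
  X <- cbind(1, X)
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + 1e-6 * mean(diag(XtX))
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- max(nrow(X) - ncol(X), 1)
  list(coef = beta, sigma = sqrt(sum(resid^2) / df))
}

pmm_draw <- function(pred_obs, y_obs, pred_mis, donors) {
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    k <- min(donors, length(d))
    cand <- order(d, seq_along(d))[seq_len(k)]  # deterministic tie-break
    y_obs[cand[sample.int(k, 1)]]
  }, numeric(1))
}

# numeric design matrix of all features except `skip`, with categorical
# features one-hot encoded from the current completed data
impute_design <- function(feat, schema, skip, extra) {
  cols <- setdiff(schema$name, skip)
  mats <- lapply(cols, function(nm) {
    kind <- schema$kind[schema$name == nm]
    if (kind == "categorical") {
      lv <- schema_levels(schema, nm)
      m <- vapply(lv[-1], function(l) as.numeric(feat[[nm]] == l),
                  numeric(nrow(feat)))
      m
    } else {
      matrix(as.numeric(feat[[nm]]), ncol = 1)
    }
  })
  X <- do.call(cbind, c(mats, if (length(extra)) list(extra)))
  X
}

#' Impute missing baseline items by chained equations
#'
#' Visits incomplete features in order of ascending missingness count;
#' within each cycle, regresses the feature's observed cells on all other
#' (currently completed) features and refills its missing cells by PMM or
#' a normal draw.  Observed cells are never changed; a dataset with no
#' missing items is returned unchanged.
#'
#' @param dataset a `trial_dataset`.
#' @param config an [imputation_config()].
#' @return the completed `trial_dataset` when `n_imputations = 1`,
#'   otherwise a list of completed datasets (downstream analyses are run
#'   per imputation; no pooling rules are applied).
#' @export
impute_chained <- function(dataset, config = imputation_config()) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(config, "imputation_config"))
  sch <- dataset$schema
  d <- dataset$data
  n_miss <- vapply(sch$name, function(nm) sum(is.na(d[[nm]])), integer(1))
  all_missing <- names(n_miss)[n_miss == nrow(d)]
  if (length(all_missing)) {
    stop_validation("column ", all_missing[1],
                    " has no observed values; cannot impute")
  }
  need_outcome <- isTRUE(config$impute_outcome) &&
    "outcome_hdd" %in% names(d) && anyNA(d$outcome_hdd)
  if (all(n_miss == 0) && !need_outcome) {
    return(if (config$n_imputations == 1) dataset else
             replicate(config$n_imputations, dataset, simplify = FALSE))
  }

  extra <- NULL
  if (config$include_arm) {
    extra <- cbind(extra, treat = as.numeric(d$arm == "active"))
  }
  if (config$include_outcome && "delta_hdd" %in% names(d) &&
      !anyNA(d$delta_hdd)) {
    extra <- cbind(extra, delta_hdd = d$delta_hdd)
  }

  visit <- names(sort(n_miss[n_miss > 0]))
  one_imputation <- function(seed) {
    with_seed(seed, {
      feat <- d[, sch$name, drop = FALSE]
      mis_idx <- lapply(visit, function(nm) which(is.na(feat[[nm]])))
      names(mis_idx) <- visit
      # initial fill: random draws from the observed values
      for (nm in visit) {
        obs <- feat[[nm]][!is.na(feat[[nm]])]
        feat[[nm]][mis_idx[[nm]]] <-
          obs[sample.int(length(obs), length(mis_idx[[nm]]), replace = TRUE)]
      }
      for (iter in if (length(visit)) seq_len(config$n_iterations) else integer(0)) {
        for (nm in visit) {
          rows <- mis_idx[[nm]]
          kind <- sch$kind[sch$name == nm]
          X <- impute_design(feat, sch, nm, extra)
          obs_rows <- setdiff(seq_len(nrow(feat)), rows)
          y <- feat[[nm]]
          if (kind == "categorical") {
            lv <- schema_levels(sch, nm)
            y_code <- match(y, lv)
            fit <- ridge_lm(X[obs_rows, , drop = FALSE], y_code[obs_rows])
            pred <- cbind(1, X) %*% fit$coef
            feat[[nm]][rows] <- lv[pmm_draw(pred[obs_rows], y_code[obs_rows],
                                            pred[rows], config$donors)]
          } else {
            fit <- ridge_lm(X[obs_rows, , drop = FALSE],
                            as.numeric(y[obs_rows]))
            pred <- as.numeric(cbind(1, X) %*% fit$coef)
            if (config$method == "pmm") {
              feat[[nm]][rows] <- pmm_draw(pred[obs_rows],
                                           as.numeric(y[obs_rows]),
                                           pred[rows], config$donors)
            } else {
              draw <- pred[rows] + stats::rnorm(length(rows), 0, fit$sigma)
              if (kind %in% c("ordinal", "binary")) {
                lo <- sch$min[sch$name == nm]
                hi <- sch$max[sch$name == nm]
                draw <- clip(round(draw), lo, hi)
              }
              feat[[nm]][rows] <- draw
            }
          }
        }
      }
      out <- dataset
      out$data[, sch$name] <- feat
      if (need_outcome) {
        X <- impute_design(feat, sch, character(0), NULL)
        X <- cbind(X, treat = as.numeric(d$arm == "active"),
                   bhdd = d$baseline_hdd)
        rows <- which(is.na(d$outcome_hdd))
        obs_rows <- which(!is.na(d$outcome_hdd))
        fit <- ridge_lm(X[obs_rows, , drop = FALSE],
                        d$outcome_hdd[obs_rows])
        pred <- as.numeric(cbind(1, X) %*% fit$coef)
        out$data$outcome_hdd[rows] <- pmm_draw(pred[obs_rows],
                                               d$outcome_hdd[obs_rows],
                                               pred[rows], config$donors)
        out$data$delta_hdd <- out$data$baseline_hdd - out$data$outcome_hdd
      }
      validate_trial(out)
      out
    })
  }

  if (config$n_imputations == 1) {
    one_imputation(config$seed)
  } else {
    lapply(seq_len(config$n_imputations), function(m) {
      one_imputation(sub_seed(config$seed, paste0("imputation", m)))
    })
  }
}

#' Per-column missingness summary
#'
#' @param dataset a `trial_dataset`.
#' @return data frame of feature name, missing count and percent, plus a
#'   subject-level summary (how many subjects miss 1, 2, ... items) as the
#'   `"by_subject"` attribute.
#' @export
missingness_summary <- function(dataset) {
  d <- dataset$data
  sch <- dataset$schema
  n_miss <- vapply(sch$name, function(nm) sum(is.na(d[[nm]])), integer(1))
  out <- data.frame(feature = sch$name, n_missing = n_miss,
                    pct_missing = round(100 * n_miss / nrow(d), 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  per_subj <- rowSums(is.na(d[, sch$name, drop = FALSE]))
  attr(out, "by_subject") <- table(items_missing = per_subj)
  out
}
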