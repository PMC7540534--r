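# Likely-responder classification and prognostic-score quantile strata.
# Stratifying the rank-ordered prognostic score into contiguous quantiles
# balances prognostic covariates between the randomized arms within each
# stratum, the subclassification analogue of matching on a balancing
# score.

#' Responder / stratification configuration
#'
#' @param threshold predicted-ΔHDD threshold in days for the
#'   likely-responder (LR) label (default 14, which guarantees at least a
#'   50% reduction from any feasible baseline of at most 28 days).
#' @param n_strata_lr quantile strata for the LR subgroup (default 2).
#' @param n_strata_full quantile strata for the whole sample (default 5).
#' @return a `responder_config` list.
#' @export
responder_config <- function(threshold = 14, n_strata_lr = 2L,
                             n_strata_full = 5L) {
  stopifnot(threshold > 0, threshold <= 28, n_strata_lr >= 2,
            n_strata_full >= 2)
  structure(list(threshold = threshold,
                 n_strata_lr = as.integer(n_strata_lr),
                 n_strata_full = as.integer(n_strata_full)),
            class = "responder_config")
}

#' Classify likely responders
#'
#' A subject is a likely responder (LR) when the predicted ΔHDD under
#' active treatment meets the threshold (closed lower bound: a score of
#' exactly 14.0 is LR); otherwise an unlikely responder (UR).
#'
#' @param scores output of [score_all()].
#' @param config a [responder_config()].
#' @return `scores` with a `label` column (`"LR"`/`"UR"`); LR/UR counts by
#'   arm are attached as attribute `"counts"`.
#' @export
classify_responders <- function(scores, config = responder_config()) {
  out <- scores
  out$label <- ifelse(scores$score >= config$threshold, "LR", "UR")
  attr(out, "counts") <- table(arm = scores$arm,
                               label = factor(out$label,
                                              levels = c("LR", "UR")))
  out
}

#' Minimum percent reduction guaranteed by a ΔHDD threshold
#'
#' With baseline HDD bounded by `max_baseline`, a reduction of at least
#' `threshold` days is a reduction of at least
#' `100 * threshold / max_baseline` percent of baseline: the analytic
#' justification for a 14-day threshold on a 28-day scale meaning "at
#' least 50%".
#'
#' @param threshold reduction threshold in days.
#' @param max_baseline maximum possible baseline HDD (default 28).
#' @return guaranteed minimum percent reduction.
#' @export
guaranteed_percent_reduction <- function(threshold, max_baseline = 28) {
  if (threshold <= 0) stop_validation("threshold must be positive")
  if (threshold > max_baseline) {
    stop_validation("threshold ", threshold, " exceeds the maximum baseline ",
                    max_baseline, "; criterion infeasible")
  }
  100 * threshold / max_baseline
}

#' Partition subjects into contiguous score quantile strata
#'
#' Sorts ascending by score (subject id as deterministic tie-break) and
#' cuts into k contiguous blocks of size `floor(n/k)` or `ceiling(n/k)`,
#' any remainder going to the highest-score blocks.  Stratum 1 holds the
#' lowest scores.
#'
#' @param scores output of [score_all()] (or any data frame with
#'   `subject_id` and `score`).
#' @param k number of strata.
#' @return a `stratum_assignment` data frame: `subject_id`, `arm` (if
#'   present), `score`, `stratum`.
#' @export
partition_quantiles <- function(scores, k) {
  n <- nrow(scores)
  k <- as.integer(k)
  if (n < k) stop_validation("cannot form ", k, " strata from ", n,
                             " subjects")
  ord <- order(scores$score, scores$subject_id)
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k)
  if (rem > 0) sizes[(k - rem + 1):k] <- base + 1L
  stratum <- rep(seq_len(k), times = sizes)
  out <- scores[ord, intersect(c("subject_id", "arm", "score"),
                               names(scores)), drop = FALSE]
  out$stratum <- stratum
  rownames(out) <- NULL
  class(out) <- c("stratum_assignment", "data.frame")
  out
}

ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(v, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

#' Within-stratum arm balance report
#'
#' For each stratum: arm counts, arm-wise mean scores, and the two-sample
#' Kolmogorov-Smirnov statistic between the arms' score distributions.
#' A stratum with an empty arm is flagged (it would make the stratified
#' treatment contrast inestimable).
#'
#' @param assignment a [partition_quantiles()] result carrying an `arm`
#'   column.
#' @param warn_empty if `TRUE` (default) an empty arm raises a warning;
#'   the report row is flagged either way.
#' @return data frame with one row per stratum.
#' @export
balance_check <- function(assignment, warn_empty = TRUE) {
  stopifnot("arm" %in% names(assignment))
  out <- do.call(rbind, lapply(split(assignment, assignment$stratum),
                               function(s) {
    a <- s$score[s$arm == "active"]
    p <- s$score[s$arm == "placebo"]
    data.frame(stratum = s$stratum[1], n = nrow(s),
               n_active = length(a), n_placebo = length(p),
               mean_score_active = if (length(a)) mean(a) else NA_real_,
               mean_score_placebo = if (length(p)) mean(p) else NA_real_,
               ks_statistic = ks_statistic(a, p),
               empty_arm = length(a) == 0 || length(p) == 0)
  }))
  rownames(out) <- NULL
  if (warn_empty && any(out$empty_arm)) {
    warning("stratum ", paste(out$stratum[out$empty_arm], collapse = ", "),
            " has an empty arm")
  }
  out
}
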