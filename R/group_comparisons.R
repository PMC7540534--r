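# Baseline LR-vs-UR comparisons and end-of-study secondary-outcome
# contrasts.  Baseline: Wilcoxon rank-sum for continuous/ordinal
# variables, chi-square (no continuity correction by default) for
# binary/categorical.  No multiplicity correction: these tables are
# descriptive; only the two primary hypotheses are error-controlled.

wilcoxon_row <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
}

chisq_row <- function(tab, correct = FALSE) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(test = "chi-square", statistic = unname(ct$statistic), p = ct$p.value)
}

#' Baseline comparison of likely vs unlikely responders
#'
#' One row per baseline variable: group summaries (mean and SD, or level
#' percentages), the test used (Wilcoxon rank-sum for continuous/ordinal;
#' chi-square for binary/categorical), its statistic and unadjusted
#' p-value.  Variables with a single observed level are flagged
#' untestable.  Baseline HDD is included alongside the schema features.
#'
#' @param dataset a `trial_dataset`.
#' @param labels a [classify_responders()] result (needs `subject_id`,
#'   `label`).
#' @param yates apply Yates continuity correction to chi-square tests
#'   (default FALSE).
#' @return data frame of comparison rows.
#' @export
baseline_compare <- function(dataset, labels, yates = FALSE) {
  d <- dataset$data
  lab <- labels$label[match(d$subject_id, labels$subject_id)]
  if (anyNA(lab)) stop_validation("labels do not cover the dataset")
  is_lr <- lab == "LR"
  sch <- dataset$schema
  vars <- rbind(data.frame(name = "baseline_hdd", kind = "continuous",
                           label = "Baseline heavy drinking days",
                           stringsAsFactors = FALSE),
                data.frame(name = sch$name, kind = sch$kind,
                           label = ifelse(is.na(sch$label), sch$name,
                                          sch$label),
                           stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    nm <- vars$name[i]
    v <- d[[nm]]
    base <- data.frame(variable = nm, label = vars$label[i],
                       n_ur = sum(!is_lr & !is.na(v)),
                       n_lr = sum(is_lr & !is.na(v)),
                       stringsAsFactors = FALSE)
    if (vars$kind[i] %in% c("continuous", "ordinal")) {
      x <- v[!is_lr & !is.na(v)]
      y <- v[is_lr & !is.na(v)]
      untestable <- length(unique(c(x, y))) < 2 || !length(x) || !length(y)
      res <- if (untestable) {
        list(test = "wilcoxon", statistic = NA_real_, p = NA_real_)
      } else {
        wilcoxon_row(x, y)
      }
      cbind(base,
            data.frame(summary_ur = sprintf("%.2f (%.2f)", mean(x),
                                            stats::sd(x)),
                       summary_lr = sprintf("%.2f (%.2f)", mean(y),
                                            stats::sd(y)),
                       test = res$test, statistic = res$statistic,
                       p = res$p, untestable = untestable,
                       stringsAsFactors = FALSE))
    } else {
      tab <- table(group = ifelse(is_lr, "LR", "UR")[!is.na(v)],
                   value = v[!is.na(v)])
      untestable <- ncol(tab) < 2 || nrow(tab) < 2
      res <- if (untestable) {
        list(test = "chi-square", statistic = NA_real_, p = NA_real_)
      } else {
        chisq_row(tab, correct = yates)
      }
      pct <- function(g) {
        p <- prop.table(tab[g, , drop = TRUE])
        paste(sprintf("%s %.1f%%", names(p), 100 * p), collapse = ", ")
      }
      cbind(base,
            data.frame(summary_ur = if ("UR" %in% rownames(tab)) pct("UR") else "",
                       summary_lr = if ("LR" %in% rownames(tab)) pct("LR") else "",
                       test = res$test, statistic = res$statistic,
                       p = res$p, untestable = untestable,
                       stringsAsFactors = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-of-study outcome contrasts within and between responder groups
#'
#' For each secondary outcome, fits the cell-means model over the four
#' arm-by-responder-group cells and performs the four pairwise contrasts
#' matching the report shape: active vs placebo within UR, within LR;
#' UR vs LR within active, within placebo.  Contrast t-tests use the
#' pooled residual variance.
#'
#' @param dataset a `trial_dataset` with `out_*` secondary outcome
#'   columns.
#' @param labels a [classify_responders()] result.
#' @param outcomes outcome column names (default: every `out_*` column).
#' @return data frame, one row per outcome: cell means (SD, n) and the
#'   four contrast p-values; contrasts touching an empty cell are `NA`
#'   and flagged.
#' @export
outcome_contrasts <- function(dataset, labels, outcomes = NULL) {
  d <- dataset$data
  if (is.null(outcomes)) outcomes <- sort(grep("^out_", names(d),
                                               value = TRUE))
  if (!length(outcomes)) stop_validation("no secondary outcome columns")
  lab <- labels$label[match(d$subject_id, labels$subject_id)]
  grp <- interaction(factor(d$arm, c("active", "placebo")),
                     factor(lab, c("UR", "LR")), sep = ":")
  rows <- lapply(outcomes, function(oc) {
    y <- d[[oc]]
    ok <- !is.na(y)
    yy <- y[ok]
    gg <- droplevels(grp[ok])
    cells <- c("active:UR", "placebo:UR", "active:LR", "placebo:LR")
    stats_cell <- lapply(cells, function(cl) {
      v <- yy[gg == cl]
      list(n = length(v), mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    })
    names(stats_cell) <- cells
    # pooled residual variance across non-empty cells
    nonempty <- cells[vapply(stats_cell, function(s) s$n > 0, logical(1))]
    ss <- sum(vapply(nonempty, function(cl) {
      v <- yy[gg == cl]
      sum((v - mean(v))^2)
    }, numeric(1)))
    df <- length(yy) - length(nonempty)
    s2 <- if (df > 0) ss / df else NA_real_
    contrast_p <- function(c1, c2) {
      a <- stats_cell[[c1]]
      b <- stats_cell[[c2]]
      if (a$n == 0 || b$n == 0 || is.na(s2) || s2 == 0) return(NA_real_)
      se <- sqrt(s2 * (1 / a$n + 1 / b$n))
      2 * stats::pt(-abs((a$mean - b$mean) / se), df)
    }
    fmt <- function(cl) sprintf("%.2f (%.2f)", stats_cell[[cl]]$mean,
                                stats_cell[[cl]]$sd)
    data.frame(outcome = oc,
               ur_active = fmt("active:UR"), ur_placebo = fmt("placebo:UR"),
               lr_active = fmt("active:LR"), lr_placebo = fmt("placebo:LR"),
               p_ur_active_vs_placebo = contrast_p("active:UR", "placebo:UR"),
               p_lr_active_vs_placebo = contrast_p("active:LR", "placebo:LR"),
               p_active_ur_vs_lr = contrast_p("active:UR", "active:LR"),
               p_placebo_ur_vs_lr = contrast_p("placebo:UR", "placebo:LR"),
               empty_cell = length(nonempty) < 4,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
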