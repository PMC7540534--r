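#' Feature schema for a trial dataset
#'
#' A feature schema declares every baseline feature of a trial: its name,
#' kind and scale bounds.  It is the contract against which CSV files are
#' validated and the source of truth for clipping in the perturbation
#' analysis.
#'
#' @param name character vector of feature names.
#' @param kind one of `"continuous"`, `"ordinal"`, `"binary"`,
#'   `"categorical"` per feature.
#' @param min,max numeric scale bounds (ignored for categorical; binary is
#'   forced to 0/1).
#' @param levels for categorical features, a single string of
#'   comma-separated level names; `NA` otherwise.
#' @param label optional human-readable item text (used in report tables).
#' @return a `feature_schema` data frame with one row per feature.
#' @export
feature_schema <- function(name, kind, min = NA_real_, max = NA_real_,
                           levels = NA_character_, label = NA_character_) {
  kind <- match.arg(kind, c("continuous", "ordinal", "binary", "categorical"),
                    several.ok = TRUE)
  sch <- data.frame(name = as.character(name), kind = kind,
                    min = as.numeric(min), max = as.numeric(max),
                    levels = as.character(levels),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  sch$min[sch$kind == "binary"] <- 0
  sch$max[sch$kind == "binary"] <- 1
  if (anyDuplicated(sch$name)) {
    stop_validation("duplicate feature name in schema: ",
                    sch$name[duplicated(sch$name)][1])
  }
  bad <- sch$kind %in% c("ordinal") & (is.na(sch$min) | is.na(sch$max))
  if (any(bad)) {
    stop_validation("ordinal feature without bounds: ", sch$name[bad][1])
  }
  class(sch) <- c("feature_schema", "data.frame")
  sch
}

schema_levels <- function(schema, name) {
  lv <- schema$levels[schema$name == name]
  strsplit(lv, ",", fixed = TRUE)[[1]]
}

#' Construct a trial dataset
#'
#' The single data currency of the pipeline: a subject-level table holding
#' arm assignment, the baseline heavy-drinking-day (HDD) count over the
#' 28-day pre-consent window, baseline features, and (optionally) daily
#' drinking statuses for the final maintenance window, the derived outcome
#' HDD count, secondary outcomes (`out_*` columns) and monthly HDD summaries
#' (`hdd_month_*` columns).
#'
#' @param data a data frame with columns `subject_id`, `arm`
#'   (`"active"`/`"placebo"`), `baseline_hdd`, optional `outcome_days`
#'   (string of `H`/`N`/`M` per day), optional `outcome_hdd`/`delta_hdd`,
#'   optional `out_*` and `hdd_month_*` columns, and one column per schema
#'   feature.
#' @param schema a [feature_schema()].
#' @param window outcome window length in days (default 28, the trial's
#'   final 4 maintenance weeks).
#' @return an object of class `trial_dataset`.
#' @export
trial_dataset <- function(data, schema, window = 28L) {
  stopifnot(is.data.frame(data), inherits(schema, "feature_schema"))
  obj <- structure(list(data = data, schema = schema,
                        window = as.integer(window)),
                   class = "trial_dataset")
  validate_trial(obj)
  obj
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d subjects (%d active, %d placebo), %d features, %d-day outcome window\n",
              nrow(x$data), sum(x$data$arm == "active"),
              sum(x$data$arm == "placebo"), nrow(x$schema), x$window))
  invisible(x)
}

#' @export
dim.trial_dataset <- function(x) c(nrow(x$data), nrow(x$schema))

#' Validate a trial dataset against its schema
#'
#' Checks arm labels, subject-id uniqueness, HDD bounds, daily status
#' alphabet and per-feature scale bounds.  Errors name the offending row
#' and column.
#'
#' @param x a `trial_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_trial <- function(x) {
  d <- x$data
  req <- c("subject_id", "arm", "baseline_hdd")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop_validation("missing required column: ", miss[1])
  if (anyDuplicated(d$subject_id)) {
    stop_validation("duplicate subject_id: ",
                    d$subject_id[duplicated(d$subject_id)][1])
  }
  bad_arm <- !d$arm %in% c("active", "placebo")
  if (any(bad_arm)) {
    stop_validation("row ", which(bad_arm)[1], " column arm: invalid value '",
                    d$arm[bad_arm][1], "'")
  }
  chk_bounds <- function(col, lo, hi) {
    v <- d[[col]]
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad)) {
      stop_validation("row ", which(bad)[1], " column ", col,
                      ": value ", v[bad][1], " outside [", lo, ", ", hi, "]")
    }
  }
  chk_bounds("baseline_hdd", 0, x$window)
  if (any(is.na(d$baseline_hdd))) {
    stop_validation("row ", which(is.na(d$baseline_hdd))[1],
                    " column baseline_hdd: missing")
  }
  if ("outcome_hdd" %in% names(d)) chk_bounds("outcome_hdd", 0, x$window)
  if ("outcome_days" %in% names(d)) {
    od <- d$outcome_days
    ok <- is.na(od) | grepl(sprintf("^[HNM]{%d}$", x$window), od)
    if (!all(ok)) {
      stop_validation("row ", which(!ok)[1], " column outcome_days: must be ",
                      x$window, " characters over {H,N,M}")
    }
  }
  sch <- x$schema
  miss_f <- setdiff(sch$name, names(d))
  if (length(miss_f)) stop_validation("missing feature column: ", miss_f[1])
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    v <- d[[nm]]
    if (sch$kind[i] == "categorical") {
      lv <- schema_levels(sch, nm)
      bad <- !is.na(v) & !v %in% lv
      if (any(bad)) {
        stop_validation("row ", which(bad)[1], " column ", nm,
                        ": level '", v[bad][1], "' not in schema")
      }
    } else if (sch$kind[i] %in% c("ordinal", "binary")) {
      bad <- !is.na(v) & (v < sch$min[i] | v > sch$max[i] | v != round(v))
      if (any(bad)) {
        stop_validation("row ", which(bad)[1], " column ", nm, ": value ",
                        v[bad][1], " outside ordinal scale [", sch$min[i],
                        ", ", sch$max[i], "]")
      }
    } else if (!is.na(sch$min[i]) || !is.na(sch$max[i])) {
      lo <- if (is.na(sch$min[i])) -Inf else sch$min[i]
      hi <- if (is.na(sch$max[i])) Inf else sch$max[i]
      bad <- !is.na(v) & (v < lo | v > hi)
      if (any(bad)) {
        stop_validation("row ", which(bad)[1], " column ", nm, ": value ",
                        v[bad][1], " outside [", lo, ", ", hi, "]")
      }
    }
  }
  invisible(x)
}

# canonical column order: id, arm, baseline, outcome columns, features
trial_column_order <- function(d, schema) {
  fixed <- c("subject_id", "arm", "baseline_hdd", "outcome_days",
             "outcome_hdd", "delta_hdd")
  out_cols <- sort(grep("^out_", names(d), value = TRUE))
  month_cols <- grep("^hdd_month_", names(d), value = TRUE)
  month_cols <- month_cols[order(as.integer(sub("^hdd_month_", "", month_cols)))]
  c(intersect(fixed, names(d)), out_cols, month_cols,
    intersect(schema$name, names(d)))
}

#' Derive the primary outcome from daily drinking records
#'
#' Computes `outcome_hdd` and the primary outcome `delta_hdd`
#' (baseline HDD minus outcome-window HDD; positive = improvement) for
#' every subject.  When daily statuses are present, days with missing
#' drinking data are counted as heavy drinking days under the default
#' `"all_heavy"` rule; `"require_complete"` instead leaves the outcome
#' missing for any subject with a missing day (for downstream imputation).
#'
#' @param dataset a `trial_dataset`.
#' @param missing_rule `"all_heavy"` (default) or `"require_complete"`.
#' @return the dataset with `outcome_hdd` and `delta_hdd` filled in.
#' @export
derive_outcome <- function(dataset, missing_rule = c("all_heavy",
                                                     "require_complete")) {
  missing_rule <- match.arg(missing_rule)
  d <- dataset$data
  has_days <- "outcome_days" %in% names(d) & !is.na(d$outcome_days %||% NA)
  if (!"outcome_hdd" %in% names(d)) d$outcome_hdd <- NA_real_
  if (any(has_days)) {
    counts <- t(vapply(d$outcome_days[has_days], function(s) {
      ch <- strsplit(s, "")[[1]]
      c(h = sum(ch == "H"), m = sum(ch == "M"))
    }, c(h = 0, m = 0)))
    o <- counts[, "h"] + counts[, "m"]
    if (missing_rule == "require_complete") o[counts[, "m"] > 0] <- NA_real_
    d$outcome_hdd[has_days] <- o
  }
  no_outcome <- !has_days & is.na(d$outcome_hdd)
  if (any(no_outcome) && missing_rule == "all_heavy" &&
      !"outcome_days" %in% names(d)) {
    stop_validation("subject ", d$subject_id[no_outcome][1],
                    ": neither daily outcome data nor outcome_hdd present")
  }
  d$delta_hdd <- d$baseline_hdd - d$outcome_hdd
  dataset$data <- d
  validate_trial(dataset)
  dataset
}

#' Read a trial dataset from CSV
#'
#' @param path path to a CSV file with a header row; missing cells are
#'   empty.
#' @param schema the [feature_schema()] the file must conform to.
#' @param window outcome window length in days.
#' @return a validated `trial_dataset`; unknown columns, out-of-bounds
#'   values and duplicate ids raise validation errors naming row and
#'   column.
#' @export
load_trial <- function(path, schema, window = 28L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  known_fixed <- c("subject_id", "arm", "baseline_hdd", "outcome_days",
                   "outcome_hdd", "delta_hdd")
  known <- c(known_fixed, schema$name)
  extra <- setdiff(names(d),
                   c(known, grep("^out_|^hdd_month_", names(d), value = TRUE)))
  if (length(extra)) stop_validation("unknown column: ", extra[1])
  char_cols <- c("subject_id", "arm", "outcome_days",
                 schema$name[schema$kind == "categorical"])
  for (nm in names(d)) {
    d[[nm]][d[[nm]] == ""] <- NA
    if (!nm %in% char_cols) {
      v <- suppressWarnings(as.numeric(d[[nm]]))
      if (any(is.na(v) & !is.na(d[[nm]]))) {
        stop_validation("column ", nm, ": non-numeric value '",
                        d[[nm]][which(is.na(v) & !is.na(d[[nm]]))[1]], "'")
      }
      d[[nm]] <- v
    }
  }
  trial_dataset(d, schema, window = window)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [load_trial()]: missing values become empty cells and
#' numeric cells are written with enough digits that a write/load round
#' trip reproduces the dataset exactly for values of up to 15 significant
#' digits.
#'
#' @param dataset a `trial_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(dataset, path) {
  validate_trial(dataset)
  d <- dataset$data[, trial_column_order(dataset$data, dataset$schema),
                    drop = FALSE]
  out <- as.data.frame(lapply(d, fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE, optional = TRUE)
  names(out) <- names(d)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a feature schema file
#'
#' A schema file is a plain CSV with columns `name`, `kind`, `min`,
#' `max`, `levels` (comma-separated, quoted) and `label`, so a trial's
#' feature contract can travel next to its data file.
#'
#' @param path schema CSV path.
#' @return [read_feature_schema()] returns a `feature_schema`;
#'   `write_feature_schema` returns `path` invisibly.
#' @export
read_feature_schema <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "kind", "min", "max", "levels", "label")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_validation("schema file missing column: ", miss[1])
  d$levels[d$levels == ""] <- NA_character_
  d$label[d$label == ""] <- NA_character_
  feature_schema(d$name, d$kind, d$min, d$max, d$levels, d$label)
}

#' @rdname read_feature_schema
#' @param schema a [feature_schema()].
#' @export
write_feature_schema <- function(schema, path) {
  utils::write.csv(as.data.frame(schema), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
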