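# internal helpers shared across modules

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a deterministic sub-seed below 2^31 from a master seed and a label.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# numeric formatting that round-trips values with <= 15 significant digits
fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else sprintf("%.15g", v)
    }, character(1))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- ""
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("lr_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
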