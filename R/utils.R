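# Shared internal helpers: seed derivation, input checking, small numerics.

#' Derive a stream-specific random seed
#'
#' Deterministically maps a base seed plus an arbitrary sequence of labels
#' (participant ids, session numbers, run indices, stage names, ...) to an
#' integer seed below 2^31. Used so that every randomized component of a
#' design or simulation draws from its own reproducible stream, without
#' correlation between streams that share a base seed.
#'
#' The hash is a 31-bit multiplicative scheme over the UTF-8 bytes of the
#' concatenated labels; it is stable across platforms and R versions.
#'
#' @param seed Integer base seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "P01", 2, "run", 3)
#' @export
derive_seed <- function(seed, ...) {
  check_scalar_number(seed, "seed")
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                         character(1)), collapse = "|")
  bytes <- as.integer(charToRaw(labels))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in bytes) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                integer = FALSE, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "devaltms_input_error")
  }
  lo_ok <- if (open) x > min else x >= min
  hi_ok <- if (open) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside the %s interval [%g, %g].",
                  name, x, if (open) "open" else "closed", min, max),
          class = "devaltms_input_error")
  }
  if (integer && x != round(x)) {
    abort(sprintf("`%s` must be an integer.", name),
          class = "devaltms_input_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")),
          class = "devaltms_input_error")
  }
  invisible(df)
}

# Fisher-Yates shuffle through R's RNG under a local seed; leaves the
# caller's RNG state untouched.
shuffle_with_seed <- function(x, seed) {
  withr::with_seed(seed, sample(x, length(x)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) stats::plogis(x)

# Writes a tibble as a plain TSV (no quoting, no row names).
write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
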