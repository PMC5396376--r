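# internal helpers shared across modules

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s",
                  name,
                  if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

# all simulators funnel randomness through here so a fixed seed gives
# byte-identical output and the caller's RNG state is untouched
with_sim_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  withr::with_seed(as.integer(seed), code)
}

# half-open interval overlap on a tibble with chrom/start/end columns
assert_intervals <- function(df, what = "intervals") {
  assert_cols(df, c("chrom", "start", "end"), what)
  if (any(df$start >= df$end)) {
    abort(sprintf("`%s` contains empty or inverted intervals (start >= end)", what))
  }
  invisible(df)
}
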