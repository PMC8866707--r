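# Internal helpers shared across modules.

# Format doubles with enough digits to round-trip IEEE 754 exactly, so that
# text serialisations (strata tables, fitted networks, report bundles) are
# bit-identical after write -> read.
fmt_dbl <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    sprintf("%.17g", v)
  }, character(1))
  unname(out)
}

parse_dbl <- function(x) {
  suppressWarnings(as.numeric(x))
}

# Derive a stream-specific seed from a master seed, kept inside 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "ldlbench_validation_error")
  }
  invisible(data)
}

assert_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort(sprintf("`%s` must be a numeric vector of length >= %d", name, min_len),
          class = "ldlbench_validation_error")
  }
  invisible(x)
}

assert_paired <- function(estimates, measured) {
  assert_numeric_vector(estimates, "estimates")
  assert_numeric_vector(measured, "measured")
  if (length(estimates) != length(measured)) {
    abort("`estimates` and `measured` must have equal length",
          class = "ldlbench_validation_error")
  }
  invisible(NULL)
}
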