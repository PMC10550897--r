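# internal helpers shared across modules

# geometric mean; errors on nonpositive input because a zero geometric mean
# makes a scale factor undefined
geo_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("geometric mean undefined: nonpositive or non-finite values present")
  }
  exp(mean(log(x)))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# derive a child seed from a base seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 7919L) %% 2147483647)
}

assert_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
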