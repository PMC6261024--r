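# Internal helpers shared across modules.

# Denominators at or below this (liters) are treated as degenerate: the
# balance equations divide by end-of-epoch body water, which must be a
# physically meaningful positive volume.
DENOM_EPS <- 1e-9

abort_validation <- function(msg, ...) {
  abort(msg, class = "natremia_validation_error", ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = "natremia_parse_error", ...)
}

abort_degenerate <- function(msg, ...) {
  abort(msg, class = "natremia_degenerate_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_validation(sprintf("`%s` must be numeric with no missing values.", name))
  }
  bad <- if (allow_zero_lower) x < lower else x <= lower
  if (any(bad | x > upper)) {
    abort_validation(sprintf(
      "`%s` must lie in [%s, %s]; offending value(s): %s.",
      name, format(lower), format(upper),
      paste(format(utils::head(x[bad | x > upper], 3)), collapse = ", ")
    ))
  }
  invisible(x)
}

# Inverse-CDF draw from a normal truncated to [lower, upper].
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}
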