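# shared internal helpers

# round half away from zero, matching printed-table style (base round() is
# banker's rounding and gives 0.5 -> 0)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# validate a factor-like column against allowed levels
check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stop_fmt("invalid %s value(s): %s (allowed: %s)", what,
             paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
  invisible(TRUE)
}
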