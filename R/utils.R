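`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (base round() uses banker's rounding, which
# would turn e.g. 58.5 into 58 and break printed-table reproduction)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# truncate toward zero at `digits` decimals (used by the R50 guideline
# column: 4.7 * 0.99217... -> 4.66, not 4.67)
trunc_decimals <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p + sign(x) * 1e-9) / p
}
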