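# Small internal helpers shared across modules.

# Round half away from zero (the convention used for printed cM and
# percentage values; base round() is half-to-even).
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == trunc(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x)
}

# Validate a probability-like scalar in [0, 1].
check_unit_interval <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  }
  x
}
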