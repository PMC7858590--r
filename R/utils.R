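# Internal helpers shared across modules.

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic sub-seed derivation; result always a valid 32-bit seed
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 + 104729 * as.double(i)) %% 2147483629)
}

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (allow_lower) x >= lower else x > lower
  ok_hi <- if (allow_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x), call. = FALSE)
  invisible(x)
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
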