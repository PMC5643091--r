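# Internal helpers shared across modules.

# Deterministic sub-seed derivation: every operation that consumes randomness
# draws from its own stream so components can be varied independently.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 100003) * 20011 + k * 104729) %% 2147483647)
}

stop_invalid <- function(msg) {
  abort(msg, class = c("deepcalseq_invalid", "deepcalseq_error"))
}

stop_insufficient <- function(msg) {
  abort(msg, class = c("deepcalseq_insufficient", "deepcalseq_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop_invalid(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Round half away from zero (reporting layer only; R's round() is
# round-half-even, which would print 2.25 nJ as 2.2).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# mean with explicit empty guard
mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
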