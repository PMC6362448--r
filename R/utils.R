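# Internal numerical helpers.

# Numerically stable log(1 + exp(x)), branch-free:
# pmax(x, 0) + log1p(exp(-|x|)) is exact in both tails and cheap on large
# arrays (no logical subsetting).
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Round half away from zero (printed tables use this, unlike base round()).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Clamp logit-scale draws so plogis() stays strictly inside (0, 1).
clamp_logit <- function(x, bound = 36) pmin(pmax(x, -bound), bound)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
}
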