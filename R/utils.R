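#' @keywords internal
"_PACKAGE"

# Round a ratio num/den (doubles holding exact integers) half-up to `digits`
# decimals using integer arithmetic, so printed-precision values such as
# 19.375 -> 19.38 are reproduced without binary-float drift.
rational_round <- function(num, den, digits = 2) {
  stopifnot(all(den > 0))
  scaled <- num * 10^digits
  q <- scaled %/% den
  r <- scaled %% den
  q <- q + as.numeric(2 * r >= den)
  q / 10^digits
}

# Half-up rounding for already-computed doubles (reporting only).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Percentage of num/den, half-up to 2 decimals, on the 0-100 scale.
pct2 <- function(num, den) rational_round(100 * num, den, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_adetrigger <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "adetrigger_error")))
}
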