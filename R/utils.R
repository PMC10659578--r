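# internal helpers: argument checks and seeded RNG

stopf <- function(fmt, ..., class = "hemekin_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ..., class = "hemekin_warning") {
  rlang::warn(sprintf(fmt, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number.", name)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) stopf("`%s` = %g is outside the allowed range [%g, %g].", name, x, lower, upper)
  invisible(x)
}

check_increasing <- function(x, name, strict = TRUE) {
  d <- diff(x)
  bad <- if (strict) any(d <= 0) else any(d < 0)
  if (length(x) < 1L || anyNA(x) || bad) {
    stopf("`%s` must be %sincreasing with no missing values.",
          name, if (strict) "strictly " else "")
  }
  invisible(x)
}

# Evaluate `expr` under a reproducible RNG state without disturbing the
# caller's stream. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# log-spaced grid, used for default stopped-flow time axes
logspace <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}

lag1_autocorr <- function(v) {
  v <- v - mean(v)
  s <- sum(v^2)
  if (s == 0) return(0)
  sum(v[-1] * v[-length(v)]) / s
}
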