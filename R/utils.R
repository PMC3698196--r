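# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Every stochastic generator in the
# package funnels through this, which is what makes them pure functions of
# their arguments.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed for sub-task `k` of a master seed, kept within
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k)) %% 2147483647)
}

db_pow <- function(x) 10 * log10(x)

# Analytic signal of a real vector via the frequency-domain construction;
# Mod() of it is the echo envelope.
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

stop_qustr <- function(...) stop(sprintf(...), call. = FALSE)
warn_qustr <- function(...) warning(sprintf(...), call. = FALSE)
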