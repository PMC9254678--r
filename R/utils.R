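# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators and stochastic summaries route through this so that every
# public function is a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Draw n values log-uniformly on [lo, hi]; spreads leverage evenly across an
# allometric (log-log) design.
runif_log <- function(n, lo, hi) {
  stopifnot(lo > 0, hi > lo)
  10^stats::runif(n, log10(lo), log10(hi))
}

# Split R-hat (Gelman et al. 2013): each chain is halved, and the classical
# potential-scale-reduction statistic is computed over the 2m half-chains.
split_rhat <- function(draws) {
  # draws: iterations x chains matrix for one parameter
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  halves <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Scalar %||%
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
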