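# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All randomized operations in the package funnel
# through this so that results are reproducible given an explicit integer seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# Normal scores of ranks (a.k.a. rank-based inverse normal transform); average
# ranks for ties. Used by the generator to impose rank couplings.
norm_score <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm(r / (length(x) + 1))
}

# Fast per-row variance of a matrix (denominator n - 1).
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu^2) / (n - 1)
}

row_medians <- function(m) {
  if (requireNamespace("matrixStats", quietly = TRUE))
    matrixStats::rowMedians(m)
  else apply(m, 1L, stats::median)
}
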