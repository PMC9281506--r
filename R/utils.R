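# internal helpers shared across modules

# Derive a stage-specific seed from one global seed; keeps stages
# reproducible yet decoupled. Result stays inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Evaluate expr under a local RNG state so callers' RNG streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Centered moving average along a vector, window truncated at the ends.
# This is the smoother applied within each chromosome during CNV
# inference. Computed as the direct windowed sum (not a cumsum trick) so
# the result is bit-identical to the naive definition.
running_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  vapply(seq_len(n), function(i) sum(x[lo[i]:hi[i]]), 0) / (hi - lo + 1L)
}

# Row-windowed moving average of a genes x cells matrix (same arithmetic
# as running_mean, vectorized across cells).
running_mean_rows <- function(m, window) {
  n <- nrow(m)
  if (window <= 1L || n == 0L) return(m)
  half <- (window - 1L) %/% 2L
  out <- m
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colSums(m[lo:hi, , drop = FALSE]) / (hi - lo + 1L)
  }
  out
}

# area under the ROC curve for scores vs a binary truth (1 = positive);
# equals the Mann-Whitney U statistic scaled to [0,1]
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
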