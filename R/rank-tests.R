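# Tie-aware two-sample and k-sample rank tests with exact small-sample
# enumeration. Base wilcox.test/kruskal.test fall back to a normal /
# chi-square approximation whenever ties are present; marker detection and
# the differential-CNV tables here need exact permutation p-values for
# small groups even with heavily tied (zero-inflated) expression, so the
# enumeration is done directly.

# Mann-Whitney U of group x vs group y (ties count 1/2)
mw_u <- function(r_all, idx1, n1, n2) {
  sum(r_all[idx1]) - n1 * (n1 + 1) / 2
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact tie-aware enumeration over all group assignments when the number
#' of assignments is at most `max_enum`, otherwise the normal approximation
#' with tie correction and continuity correction. Exact two-sided p counts
#' assignments whose U lies at least as far from its permutation mean as
#' the observed U.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param max_enum assignment-count cap for the exact path.
#' @return list(statistic = U of x, p_value, method).
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater",
                                               "less"),
                         max_enum = 20000) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups need observations")
  vals <- c(x, y)
  r <- rank(vals)
  u <- mw_u(r, seq_len(n1), n1, n2)
  if (stats::var(vals) == 0)
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  n_assign <- choose(n, n1)
  if (n_assign <= max_enum) {
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, function(idx) mw_u(r, idx, n1, n2))
    p <- switch(alternative,
      two.sided = mean(abs(us - mean(us)) >= abs(u - mean(us)) - 1e-9),
      greater = mean(us >= u - 1e-9),
      less = mean(us <= u + 1e-9))
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  ties <- table(vals)
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tiecor)
  mu <- n1 * n2 / 2
  cc <- 0.5
  z <- switch(alternative,
    two.sided = (u - mu - sign(u - mu) * cc) / sqrt(sigma2),
    greater = (u - mu - cc) / sqrt(sigma2),
    less = (u - mu + cc) / sqrt(sigma2))
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  list(statistic = u, p_value = min(1, p), method = "normal")
}

# all distinct assignments of n items into groups of sizes ns (list of
# index matrices is too large to hold; recurse and apply FUN, collecting
# the statistic)
enumerate_assignments <- function(n, ns, fun) {
  out <- numeric(0)
  recurse <- function(avail, sizes, groups) {
    if (length(sizes) == 1L) {
      out[[length(out) + 1L]] <<- fun(c(groups, list(avail)))
      return(invisible())
    }
    cs <- utils::combn(length(avail), sizes[1])
    for (j in seq_len(ncol(cs))) {
      pick <- avail[cs[, j]]
      recurse(setdiff(avail, pick), sizes[-1], c(groups, list(pick)))
    }
  }
  recurse(seq_len(n), ns, list())
  out
}

kw_h <- function(r, groups_idx, n) {
  s <- sum(vapply(groups_idx,
                  function(ix) sum(r[ix])^2 / length(ix), 0))
  12 / (n * (n + 1)) * s - 3 * (n + 1)
}

#' Kruskal-Wallis rank test with exact small-sample enumeration
#'
#' Tie-corrected H statistic; p by full enumeration of the group
#' assignments when their count is at most `max_enum`, else the chi-square
#' approximation (matching `stats::kruskal.test`).
#'
#' @param values numeric responses.
#' @param groups group labels (>= 2 groups, each non-empty).
#' @param max_enum assignment-count cap for the exact path.
#' @return list(statistic = H, p_value, df, method).
#' @export
kruskal_wallis <- function(values, groups, max_enum = 20000) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("empty group")
  n <- length(values)
  r <- rank(values)
  idx <- split(seq_len(n), groups)
  ties <- table(values)
  ccor <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (ccor == 0)
    return(list(statistic = 0, p_value = 1, df = nlevels(groups) - 1,
                method = "degenerate"))
  h <- kw_h(r, idx, n) / ccor
  ns <- lengths(idx)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(ns + 1)))
  if (n_assign <= max_enum) {
    hs <- enumerate_assignments(n, ns, function(g) kw_h(r, g, n) / ccor)
    p <- mean(hs >= h - 1e-9)
    return(list(statistic = h, p_value = p, df = nlevels(groups) - 1,
                method = "exact"))
  }
  df <- nlevels(groups) - 1
  list(statistic = h, p_value = stats::pchisq(h, df, lower.tail = FALSE),
       df = df, method = "chisq")
}

# vectorized normal-approximation Mann-Whitney across matrix rows
# (genes x cells); returns U, z-based two-sided p and group means
mw_rows <- function(v, in_group, ranks = NULL) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  if (is.null(ranks)) ranks <- t(apply(v, 1, rank))
  u <- rowSums(ranks[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  tiecor <- apply(v, 1, function(x) {
    tt <- table(x); sum(tt^3 - tt)
  }) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tiecor)
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(pmax(sigma2, 1e-300))
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1
  list(u = u, p = pmin(1, p))
}
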