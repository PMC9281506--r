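#' Two-sample Fisher-Pitman permutation test
#'
#' Permutation test on the linear statistic T = sum of responses in the
#' first group. `exact` enumerates every assignment of observations to
#' groups; the two-sided p doubles the smaller tail probability of the
#' observed T, capped at 1. `asymptotic` standardizes T by its exact
#' permutation mean and variance and doubles the normal tail.
#' `monte_carlo` samples assignments, with the +1 correction so p is
#' never 0.
#'
#' @param responses numeric vector.
#' @param groups two-group labels aligned with `responses`.
#' @param mode `"asymptotic"`, `"exact"` or `"monte_carlo"`.
#' @param n_draws Monte-Carlo draws.
#' @param rng_seed Monte-Carlo seed.
#' @param max_enum assignment cap above which `exact` refuses to run.
#' @return list(statistic = observed T, z, p_value, method,
#'   n = group sizes).
#' @export
fisher_pitman <- function(responses, groups,
                          mode = c("asymptotic", "exact", "monte_carlo"),
                          n_draws = 10000, rng_seed = 0L,
                          max_enum = 1e6) {
  mode <- match.arg(mode)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  ns <- table(groups)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  if (!all(is.finite(responses))) stop("responses must be finite")
  x <- responses
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n <- length(x)
  t_obs <- sum(x[g1])
  mu <- n1 * mean(x)
  if (stats::var(x) == 0)
    return(list(statistic = t_obs, z = 0, p_value = 1,
                method = "degenerate", n = as.integer(ns)))
  pop_var <- sum((x - mean(x))^2) / n
  sigma2 <- n1 * (n - n1) / (n - 1) * pop_var
  z <- (t_obs - mu) / sqrt(sigma2)
  p <- switch(mode,
    asymptotic = min(1, 2 * stats::pnorm(-abs(z))),
    exact = {
      if (choose(n, n1) > max_enum)
        stop("too many assignments for exact enumeration")
      ts <- utils::combn(n, n1, function(idx) sum(x[idx]))
      min(1, 2 * min(mean(ts <= t_obs + 1e-9), mean(ts >= t_obs - 1e-9)))
    },
    monte_carlo = with_seed(derive_seed(rng_seed, "fisher_pitman"), {
      ts <- vapply(seq_len(n_draws),
                   function(i) sum(x[sample.int(n, n1)]), 0)
      lo <- (1 + sum(ts <= t_obs + 1e-9)) / (n_draws + 1)
      hi <- (1 + sum(ts >= t_obs - 1e-9)) / (n_draws + 1)
      min(1, 2 * min(lo, hi))
    }))
  list(statistic = t_obs, z = z, p_value = p, method = mode,
       n = as.integer(ns))
}

#' Cell-type composition contrast between two groups of units
#'
#' Builds per-cell-type responses and applies the two-sample
#' Fisher-Pitman test per type with BH adjustment across types. With
#' `unit = "cell"` the observational units are cells and the response for
#' type t is the 0/1 indicator of a cell being of type t (the
#' within-sample subclone contrast). With `unit = "sample"` the units are
#' samples and the response is the sample's proportion of type t (the
#' primary-vs-recurrent contrast).
#'
#' @param cell_meta data.frame with `cell_id`, a cell-type column and the
#'   grouping column.
#' @param group_col column holding the two-level grouping (e.g.
#'   `"subclone"` or `"condition"`).
#' @param type_col cell-type column name.
#' @param unit `"cell"` or `"sample"` (requires a `sample_id` column).
#' @param mode Fisher-Pitman mode.
#' @param alpha significance level on q.
#' @return data.frame per cell type (cell_type, statistic, p_value,
#'   q_value, significant) plus attribute `"proportions"` with the
#'   group-by-type proportion table.
#' @export
composition_contrast <- function(cell_meta, group_col, type_col = "cell_type",
                                 unit = c("cell", "sample"),
                                 mode = "asymptotic", alpha = 0.05) {
  unit <- match.arg(unit)
  keep <- !is.na(cell_meta[[group_col]]) & !is.na(cell_meta[[type_col]])
  cm <- cell_meta[keep, , drop = FALSE]
  grp <- as.factor(as.character(cm[[group_col]]))
  if (nlevels(grp) != 2) stop("grouping must have exactly two levels")
  if (any(table(grp) == 0)) stop("a group has no cells")
  types <- sort(unique(cm[[type_col]]))
  if (unit == "cell") {
    resp_group <- grp
    resp_fun <- function(t) as.numeric(cm[[type_col]] == t)
  } else {
    tab <- prop.table(table(cm$sample_id, cm[[type_col]]), margin = 1)
    samp_grp <- tapply(as.character(grp), cm$sample_id,
                       function(g) g[1])[rownames(tab)]
    if (min(table(samp_grp)) < 2)
      stop("need at least 2 samples per group")
    resp_group <- factor(samp_grp)
    resp_fun <- function(t) as.numeric(tab[, t])
  }
  res <- lapply(types, function(t)
    fisher_pitman(resp_fun(t), resp_group, mode = mode))
  out <- data.frame(cell_type = types,
                    statistic = vapply(res, `[[`, 0, "statistic"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < alpha
  attr(out, "proportions") <- prop.table(
    table(cm[[group_col]], cm[[type_col]]), margin = 1)
  out
}

#' Pearson correlation matrix with per-pair p-values
#'
#' @param ... named numeric vectors of equal length (>= 3), or a single
#'   data.frame/matrix of columns to correlate.
#' @return list(r = correlation matrix, p = t-based two-sided p-value
#'   matrix, n). Zero-variance vectors yield NA with a warning.
#' @export
correlate <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1 && (is.data.frame(args[[1]]) ||
                                 is.matrix(args[[1]]))) {
    as.data.frame(args[[1]])
  } else as.data.frame(args)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations")
  k <- ncol(x)
  if (any(vapply(x, stats::sd, 0) == 0))
    warning("zero-variance input; correlations undefined for it")
  r <- suppressWarnings(stats::cor(x))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(r = r, p = p, n = n)
}
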