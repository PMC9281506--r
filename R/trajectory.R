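#' Per-cell stemness/differentiation trajectory score
#'
#' The undifferentiated component is the module score of the stem-like
#' endpoint markers (NSC-like cells of the stem-dominant subclone); the
#' differentiated component is the module score of the differentiated
#' endpoint markers (EpC-like cells of the other subclone). The trajectory
#' score is their difference — undifferentiated minus differentiated — so
#' higher means more stem-like. Both components share the same layer,
#' binning parameters and control-gene seed so they are directly
#' comparable.
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param undiff_markers marker set of the stem-like endpoint
#'   ([signature_set] or gene vector).
#' @param diff_markers marker set of the differentiated endpoint.
#' @param n_bins,n_ctrl_per_gene,rng_seed passed to [module_score()].
#' @return data.frame (cell_id, undiff_traj_score, diff_traj_score,
#'   trajectory_score).
#' @export
trajectory_score <- function(E, undiff_markers, diff_markers,
                             n_bins = 25, n_ctrl_per_gene = 100,
                             rng_seed = 0L) {
  up <- module_score(E, undiff_markers, n_bins, n_ctrl_per_gene, rng_seed)
  dn <- module_score(E, diff_markers, n_bins, n_ctrl_per_gene, rng_seed)
  data.frame(cell_id = E$cell_ids,
             undiff_traj_score = unname(up),
             diff_traj_score = unname(dn),
             trajectory_score = unname(up - dn),
             stringsAsFactors = FALSE)
}

#' Sample-level trajectory summary and high/low stratification
#'
#' Per-sample mean trajectory score; samples whose mean exceeds the
#' unweighted mean of sample means are "high", the rest (including exact
#' ties) "low".
#'
#' @param traj a [trajectory_score()] table.
#' @param cell_meta data.frame with `cell_id` and `sample_id`.
#' @return data.frame (sample_id, mean_score, n_cells, group); with a
#'   single sample the group column is NA.
#' @export
summarize_by_sample <- function(traj, cell_meta) {
  m <- merge(traj, cell_meta[, c("cell_id", "sample_id")], by = "cell_id")
  means <- tapply(m$trajectory_score, m$sample_id, mean)
  out <- data.frame(sample_id = names(means),
                    mean_score = as.numeric(means),
                    n_cells = as.integer(table(m$sample_id)[names(means)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(out) < 2) {
    out$group <- NA_character_
    return(out)
  }
  cutpoint <- mean(out$mean_score)
  out$group <- ifelse(out$mean_score > cutpoint, "high", "low")
  out
}

#' Rank-based comparison of score distributions between groups
#'
#' @param scores numeric responses.
#' @param groups group labels.
#' @param test `"mann_whitney"` (2 groups) or `"kruskal_wallis"` (>= 2).
#' @return list(statistic, p_value, method, n = per-group sizes).
#' @export
compare_groups <- function(scores, groups,
                           test = c("mann_whitney", "kruskal_wallis")) {
  test <- match.arg(test)
  groups <- as.factor(as.character(groups))
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("need at least two non-empty groups")
  if (test == "mann_whitney") {
    if (nlevels(groups) != 2)
      stop("mann_whitney requires exactly two groups")
    lv <- levels(groups)
    r <- mann_whitney(scores[groups == lv[1]], scores[groups == lv[2]])
  } else {
    r <- kruskal_wallis(scores, groups)
  }
  list(statistic = r$statistic, p_value = r$p_value,
       method = paste(test, r$method, sep = "/"),
       n = as.integer(table(groups)))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group with right censoring and the
#' two-group log-rank chi-square (survival::survdiff), p from
#' chi-square(1). With no events the p-value is flagged undefined.
#'
#' @param records data.frame with columns `time`, `event` (logical or
#'   0/1) and `group`.
#' @return list(curves = data.frame(group, time, surv, n_risk, n_event)
#'   including the t = 0 point, chisq, p_value, n_events, flag).
#' @export
km_logrank <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (any(records$time < 0)) stop("negative survival times")
  grp <- as.factor(as.character(records$group))
  if (nlevels(grp) != 2) stop("log-rank comparison needs exactly 2 groups")
  ev <- as.integer(as.logical(records$event))
  fit <- survival::survfit(survival::Surv(records$time, ev) ~ grp)
  strata_names <- sub("^grp=", "", rep(names(fit$strata),
                                       fit$strata %||% length(fit$time)))
  curves <- data.frame(group = strata_names, time = fit$time,
                       surv = fit$surv, n_risk = fit$n.risk,
                       n_event = fit$n.event, stringsAsFactors = FALSE)
  zero <- data.frame(group = levels(grp), time = 0, surv = 1,
                     n_risk = as.integer(table(grp)), n_event = 0L,
                     stringsAsFactors = FALSE)
  curves <- rbind(zero, curves)
  curves <- curves[order(curves$group, curves$time), ]
  if (sum(ev) == 0) {
    warning("no events observed; log-rank p undefined")
    return(list(curves = curves, chisq = NA_real_, p_value = NA_real_,
                n_events = 0L, flag = "no_events"))
  }
  sd <- survival::survdiff(survival::Surv(records$time, ev) ~ grp)
  list(curves = curves, chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_events = sum(ev), flag = "ok")
}

#' Median survival time from a KM curve table
#'
#' First time at which the estimated survival drops to 0.5 or below.
#'
#' @param curves the `curves` element of [km_logrank()].
#' @return named numeric, one median (possibly NA) per group.
#' @export
km_median <- function(curves) {
  vapply(split(curves, curves$group), function(cv) {
    hit <- cv$time[cv$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, 0)
}
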