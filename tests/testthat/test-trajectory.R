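test_that("trajectory score is the exact difference and self-cancels", {
  cx <- default_cohort()
  mk <- cx$co$trajectory_markers
  tr <- trajectory_score(cx$E, mk$undiff, mk$diff, rng_seed = 5)
  expect_lt(max(abs(tr$trajectory_score -
                      (tr$undiff_traj_score - tr$diff_traj_score))), 1e-12)
  # identical marker sets cancel exactly (shared control seed)
  tr0 <- trajectory_score(cx$E, mk$undiff, mk$undiff, rng_seed = 5)
  expect_true(all(tr0$trajectory_score == 0))
  # antisymmetry under marker-set swap
  trs <- trajectory_score(cx$E, mk$diff, mk$undiff, rng_seed = 5)
  expect_equal(trs$trajectory_score, -tr$trajectory_score)
})

test_that("trajectory score recovers the planted differentiation gradient", {
  cx <- default_cohort()
  mk <- cx$co$trajectory_markers
  tr <- trajectory_score(cx$E, mk$undiff, mk$diff, rng_seed = 5)
  tc <- cx$truth
  mal <- tc$true_malignant
  rho <- cor(tr$trajectory_score[mal], tc$true_pseudotime[mal],
             method = "spearman")
  expect_lte(rho, -0.8)
  stem <- tr$trajectory_score[tc$true_type == "NSC-like"]
  diffd <- tr$trajectory_score[tc$true_type == "EpC-like"]
  expect_gte(clonetraj:::auroc(c(stem, diffd),
                               rep(c(1, 0), c(length(stem),
                                              length(diffd)))), 0.95)
})

test_that("sample summaries split at the mean of sample means", {
  tr <- data.frame(cell_id = c("a", "b", "c", "d"),
                   undiff_traj_score = 0, diff_traj_score = 0,
                   trajectory_score = c(-1, -1, 1, 1))
  cm <- data.frame(cell_id = c("a", "b", "c", "d"),
                   sample_id = c("s1", "s1", "s2", "s2"))
  sm <- summarize_by_sample(tr, cm)
  expect_equal(sm$group, c("low", "high"))
  expect_equal(sm$mean_score, c(-1, 1))
  # exact ties go low
  tr$trajectory_score <- rep(2, 4)
  expect_equal(summarize_by_sample(tr, cm)$group, c("low", "low"))
  # single sample: no split
  cm$sample_id <- "s1"
  expect_true(is.na(summarize_by_sample(tr, cm)$group))
})

test_that("group comparisons behave at the null and under shifts", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(compare_groups(c(x, y), rep(c("a", "b"), each = 3))$p_value,
               1)
  set.seed(6)
  v <- c(rnorm(200), rnorm(200, 0.6))
  g <- rep(c("a", "b"), each = 200)
  expect_lt(compare_groups(v, g)$p_value, 1e-4)
  expect_lt(compare_groups(v, g, test = "kruskal_wallis")$p_value, 1e-4)
  expect_error(compare_groups(v, rep("a", 400)), "two")
  expect_error(compare_groups(1:6, rep(letters[1:3], 2),
                              test = "mann_whitney"), "exactly two")
})

test_that("Kaplan-Meier curves and the log-rank test match first principles", {
  rec <- data.frame(time = c(1, 2, 3, 10, 20, 30), event = TRUE,
                    group = rep(c("A", "B"), each = 3))
  km <- km_logrank(rec)
  expect_equal(unname(km_median(km$curves)), c(2, 20))
  expect_equal(km$chisq,
               logrank_chisq_oracle(rec$time, rec$event, rec$group == "A"))
  expect_equal(km$p_value, pchisq(km$chisq, 1, lower.tail = FALSE))
  # curve starts at 1 and never increases
  for (cv in split(km$curves, km$curves$group)) {
    expect_equal(cv$surv[cv$time == 0], 1)
    expect_true(all(diff(cv$surv[order(cv$time)]) <= 1e-12))
  }
  # identical groups: statistic 0
  rec2 <- data.frame(time = rep(c(1, 2, 3), 2), event = TRUE,
                     group = rep(c("A", "B"), 3))
  expect_equal(km_logrank(rec2)$chisq, 0, tolerance = 1e-12)
  # all censored: flat curves, flagged p
  rec3 <- data.frame(time = c(5, 6, 7, 8), event = FALSE,
                     group = c("A", "A", "B", "B"))
  expect_warning(km3 <- km_logrank(rec3), "no events")
  expect_true(is.na(km3$p_value))
  expect_true(all(km3$curves$surv == 1))
})

test_that("log-rank p agrees with an independent permutation null", {
  set.seed(41)
  n <- 40
  rec <- data.frame(time = c(rexp(n / 2, 0.2), rexp(n / 2, 0.55)),
                    event = TRUE, group = rep(c("A", "B"), each = n / 2))
  km <- km_logrank(rec)
  # permutation null of the same statistic, vectorized via reverse cumsums
  ord <- order(rec$time)
  g <- as.integer(rec$group[ord] == "A")
  nrisk <- n:1
  perm_chisq <- function(gv) {
    n1 <- rev(cumsum(rev(gv)))
    O <- sum(gv); E <- sum(n1 / nrisk)
    V <- sum((n1 / nrisk) * (1 - n1 / nrisk))
    (O - E)^2 / V
  }
  expect_equal(perm_chisq(g), km$chisq, tolerance = 1e-10)
  draws <- 2e4
  null <- vapply(seq_len(draws), function(i) perm_chisq(sample(g)), 0)
  p_perm <- mean(null >= km$chisq)
  se <- sqrt(max(p_perm * (1 - p_perm), 1e-6) / draws)
  expect_lt(abs(p_perm - km$p_value), 3 * se + 0.01)
})

test_that("high-trajectory samples die sooner on the planted cohort", {
  cx <- default_cohort()
  mk <- cx$co$trajectory_markers
  tr <- trajectory_score(cx$E, mk$undiff, mk$diff, rng_seed = 5)
  cm <- data.frame(cell_id = cx$truth$cell_id,
                   sample_id = cx$truth$sample_id)
  sm <- summarize_by_sample(tr, cm)
  sv <- merge(cx$co$truth$samples, sm)
  expect_lt(mean(sv$survival_time[sv$group == "high"]),
            mean(sv$survival_time[sv$group == "low"]))
})
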