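test_that("a gene exclusive to one group is reported as its marker", {
  cx <- two_program_E()
  lab <- ifelse(cx$hi, "hi", "lo")
  v <- dense_values(cx$E)
  v["g001", !cx$hi] <- 0          # exclusive to hi
  E <- expr_matrix(v, cx$E$gene_ids, cx$E$cell_ids, "E")
  mk <- find_markers(E, lab)
  row <- mk[mk$gene_id == "g001" & mk$group == "hi", ]
  expect_equal(nrow(row), 1)
  expect_true(row$marker)
  expect_equal(row$pct_out_group, 0)
  expect_gt(row$log_fold_change, 0)
})

test_that("marker p-values match the exact enumeration oracle", {
  set.seed(14)
  m <- matrix(rpois(10 * 8, 3), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("c%02d", 1:8)))
  E <- normalize_E(expr_matrix(m, layer = "counts"))
  lab <- rep(c("a", "b"), each = 4)
  mk <- find_markers(E, lab, min_pct = 0, min_logfc = 0)
  v <- dense_values(E)
  for (i in seq_len(nrow(mk))) {
    g <- mk$gene_id[i]
    ing <- lab == mk$group[i]
    expect_equal(mk$p_value[i], mw_enum_oracle(v[g, ing], v[g, !ing]))
  }
})

test_that("permuted labels produce essentially no markers", {
  set.seed(15)
  m <- matrix(rpois(300 * 60, 2), 300, 60,
              dimnames = list(sprintf("g%03d", 1:300),
                              sprintf("c%03d", 1:60)))
  E <- normalize_E(expr_matrix(m, layer = "counts"))
  lab <- sample(rep(c("a", "b"), 30))
  mk <- find_markers(E, lab, min_pct = 0, min_logfc = 0)
  expect_lt(mean(mk$marker), 0.01)
})

test_that("small groups are skipped with a warning", {
  cx <- two_program_E()
  lab <- ifelse(cx$hi, "hi", "lo")
  lab[1:2] <- "tiny"
  expect_warning(find_markers(cx$E, lab), "fewer than 3")
})

test_that("module score is centered, seeded and permutation-equivariant", {
  cx <- two_program_E(n_genes = 200, n_cells = 100, n_sig = 20)
  # signature = every gene, one bin: control population equals signature
  s_all <- module_score(cx$E, cx$E$gene_ids, n_bins = 1,
                        n_ctrl_per_gene = 200, rng_seed = 1)
  expect_lt(max(abs(s_all)), 0.05)
  # determinism and cell-permutation equivariance
  s1 <- module_score(cx$E, cx$sig, rng_seed = 7)
  s2 <- module_score(cx$E, cx$sig, rng_seed = 7)
  expect_identical(s1, s2)
  perm <- sample(length(cx$E$cell_ids))
  Ep <- subset_expr(cx$E, cells = cx$E$cell_ids[perm])
  sp <- module_score(Ep, cx$sig, rng_seed = 7)
  expect_equal(sp, s1[cx$E$cell_ids[perm]])
  # planted program: carriers score higher (AUROC ~ 1)
  expect_gte(clonetraj:::auroc(s1, cx$hi), 0.99)
  expect_error(module_score(cx$E, c("nope1", "nope2")), "no signature gene")
  expect_warning(module_score(cx$E, c(cx$sig, "absent-gene"), rng_seed = 1),
                 "absent")
})

test_that("SE classification recovers planted types and breaks ties stably", {
  cx <- default_cohort()
  cl <- default_clusters()
  se <- se_classify(cx$E, cl, cx$co$signatures, rng_seed = 3)
  maj <- vapply(split(cx$truth$true_type, cl),
                function(x) names(which.max(table(x))), "")
  expect_gte(mean(se$assignment[names(maj)] == maj), 0.95)
  # invariance to cluster label renaming
  se2 <- se_classify(cx$E, paste0("k", cl), cx$co$signatures, rng_seed = 3)
  expect_equal(unname(se2$assignment[paste0("k", names(maj))]),
               unname(se$assignment[names(maj)]))
  # duplicated signature forces a tie on its best cluster
  sigs <- cx$co$signatures[c("NSC-like", "NSC-like")]
  names(sigs) <- c("first", "second")
  w <- capture_warnings(se_classify(cx$E, cl, sigs, rng_seed = 3))
  expect_true(any(grepl("tie", w)))
})

test_that("rSE against an independent reference agrees with SE", {
  cx <- default_cohort()
  cl <- default_clusters()
  se <- se_classify(cx$E, cl, cx$co$signatures, rng_seed = 3)
  ref <- default_cohort(99L)
  rse <- rse_classify(cx$E, cl, ref$E, ref$truth$true_type,
                      se_result = se, rng_seed = 3)
  expect_gte(rse$agreement$concordance, 0.9)
  expect_gt(rse$agreement$score_correlation, 0.5)
})

test_that("a structureless query cluster is flagged unassigned", {
  set.seed(16)
  m <- matrix(rpois(150 * 90, 2), 150, 90,
              dimnames = list(sprintf("g%03d", 1:150),
                              sprintf("c%03d", 1:90)))
  m[1:3, 1:30] <- rpois(90, 12)           # cluster 1 program
  m[4:6, 31:60] <- rpois(90, 12)          # cluster 2 program
  # the third cluster is an exact 50/50 mixture of the two programs, so
  # no gene distinguishes it from the rest and it yields no markers
  m[1:3, 61:75] <- rpois(45, 12)
  m[4:6, 76:90] <- rpois(45, 12)
  E <- normalize_E(expr_matrix(m, layer = "counts"))
  cl <- rep(c("c1", "c2", "noise"), each = 30)
  ref <- two_program_E()
  out <- suppressWarnings(
    rse_classify(E, cl, ref$E, ifelse(ref$hi, "T1", "T2"), rng_seed = 1))
  expect_true("noise" %in% out$unassigned)
  expect_true(is.na(out$assignment[["noise"]]))
})

test_that("undifferentiation score tracks planted pseudotime", {
  cx <- default_cohort()
  mal <- cx$truth$true_malignant
  us <- undiff_score(cx$E)
  expect_equal(min(us), 0)
  expect_equal(max(us), 1)
  rho <- cor(us[mal], cx$truth$true_pseudotime[mal], method = "spearman")
  expect_lte(rho, -0.7)
  # stem endpoint scores exceed the differentiated endpoint
  nsc <- us[cx$truth$true_type == "NSC-like"]
  epc <- us[cx$truth$true_type == "EpC-like"]
  expect_gt(mean(nsc) - mean(epc), 0)
  expect_lt(wilcox.test(nsc, epc)$p.value, 0.01)
})

test_that("undifferentiation score degrades gracefully on constant input", {
  m <- matrix(3, 30, 10, dimnames = list(sprintf("g%02d", 1:30),
                                         sprintf("c%02d", 1:10)))
  E <- expr_matrix(m, layer = "E")
  expect_warning(us <- undiff_score(E, n_top_genes = 5), "constant")
  expect_true(all(us == 0.5))
})

test_that("signature files round-trip through the two-column TSV form", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sigs.tsv")
  write.table(data.frame(set = rep(c("T1", "T2"), c(2, 3)),
                         gene = c("a", "b", "c", "d", "e")),
              p, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  sigs <- read_signatures(p)
  expect_named(sigs, c("T1", "T2"))
  expect_equal(sigs$T2$genes, c("c", "d", "e"))
  expect_error(signature_set("empty", character(0)), "empty")
})
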