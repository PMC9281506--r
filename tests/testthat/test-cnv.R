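test_that("reference sampling is sized, deterministic and clamped", {
  cm <- data.frame(cell_id = sprintf("c%03d", 1:500),
                   cell_type = rep(c("OPC", "Other"), c(400, 100)),
                   stringsAsFactors = FALSE)
  r1 <- sample_reference(cm, "OPC", 300, rng_seed = 3)
  r2 <- sample_reference(cm, "OPC", 300, rng_seed = 3)
  expect_identical(r1, r2)
  expect_equal(length(unique(r1)), 300)
  expect_true(all(cm$cell_type[match(r1, cm$cell_id)] == "OPC"))
  expect_warning(r3 <- sample_reference(cm, "Other", 300), "using all")
  expect_equal(length(r3), 100)
  expect_error(sample_reference(cm, "Astro", 10), "no cells")
})

test_that("the moving average equals a brute-force windowed mean", {
  set.seed(33)
  x <- rnorm(30)                       # a 30-gene toy chromosome
  for (w in c(3, 5, 101)) {
    oracle <- vapply(seq_along(x), function(i) {
      half <- (w - 1) / 2
      win <- x[max(1, i - half):min(length(x), i + half)]
      sum(win) / length(win)
    }, 0)
    expect_identical(clonetraj:::running_mean(x, w), oracle)
    m <- cbind(x, rev(x))
    expect_identical(unname(clonetraj:::running_mean_rows(m, w)[, 1]),
                     oracle)
  }
  expect_identical(clonetraj:::running_mean(x, 1), x)
  # shift-equivariance along the gene axis
  expect_equal(clonetraj:::running_mean(x + 5, 5),
               clonetraj:::running_mean(x, 5) + 5)
})

test_that("reference-only input calibrates to the normal copy", {
  cx <- default_cohort()
  opc <- cx$truth$cell_id[cx$truth$true_type == "OPC"]
  E <- subset_expr(cx$E, cells = opc)
  cnv <- infer_cnv(E, cx$co$genes, opc)
  expect_lt(mean(abs(cnv$values - 1)), 0.05)
  expect_true(all(cnv$values >= 0 & cnv$values <= 2))
  expect_error(infer_cnv(cx$E, cx$co$genes, opc, window = 100), "odd")
})

test_that("planted segments are recovered in the copy proxies", {
  cx <- default_cohort(); dn <- default_cnv()
  tc <- cx$truth
  ch <- dn$cnv$genes$chrom
  s1 <- tc$cell_id[tc$true_malignant & tc$true_subclone == "subclone1"]
  s2 <- tc$cell_id[tc$true_malignant & tc$true_subclone == "subclone2"]
  chr1_carrier <- colMeans(dn$cnv$values[ch == "chr1", s1])
  chr1_other <- colMeans(dn$cnv$values[ch == "chr1", s2])
  expect_gt(mean(chr1_carrier), mean(chr1_other))
  # gain direction recovered in nearly every carrier cell
  expect_gte(mean(chr1_carrier > median(chr1_other)), 0.99)
  chr2_carrier <- colMeans(dn$cnv$values[ch == "chr2", s2])
  chr2_other <- colMeans(dn$cnv$values[ch == "chr2", s1])
  expect_gte(mean(chr2_carrier < median(chr2_other)), 0.99)
})

test_that("cnv_level is exact on constructed cases and well-behaved", {
  vals <- matrix(1, 4, 3, dimnames = list(letters[1:4], c("x", "y", "z")))
  genes <- data.frame(gene_id = letters[1:4], chrom = "chr1",
                      start = 0:3 * 10, end = 0:3 * 10 + 5)
  cm <- structure(list(values = vals, genes = genes,
                       reference_cell_ids = "x", window = 3L),
                  class = "cnv_matrix")
  expect_equal(unname(cnv_level(cm)), c(0, 0, 0))     # all-normal: exactly 0
  vals2 <- vals; vals2["a", "y"] <- 2
  cm$values <- vals2
  expect_equal(unname(cnv_level(cm)), c(0, 1, 0))     # one gene at c = 2
  # additivity over disjoint gene sets and gene-order invariance
  set.seed(8)
  cm$values <- matrix(runif(12, 0, 2), 4, 3,
                      dimnames = dimnames(vals))
  lv <- cnv_level(cm)
  top <- cm; top$values <- cm$values[1:2, , drop = FALSE]
  top$genes <- genes[1:2, ]
  bot <- cm; bot$values <- cm$values[3:4, , drop = FALSE]
  bot$genes <- genes[3:4, ]
  expect_equal(lv, cnv_level(top) + cnv_level(bot))
  shuf <- cm; shuf$values <- cm$values[c(3, 1, 4, 2), ]
  shuf$genes <- genes[c(3, 1, 4, 2), ]
  expect_equal(cnv_level(shuf), lv)
})

test_that("subclone calling recovers the planted clones and handles edge cases", {
  cx <- default_cohort(); dn <- default_cnv()
  tc <- cx$truth
  mal <- tc$cell_id[tc$true_malignant]
  sr <- call_subclones(dn$cnv, cells = mal)
  expect_equal(sr$k, 2L)
  expect_gte(clonetraj:::adjusted_rand_index(
    sr$labels[mal], tc$true_subclone[match(mal, tc$cell_id)]), 0.9)
  # duplicated cells land in the same subclone
  dup <- sr$labels[c("C00001", "C00001")]
  expect_equal(dup[[1]], dup[[2]])
  # identical profiles collapse to one flagged cluster
  flat <- dn$cnv
  flat$values <- matrix(1, 20, 10,
                        dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  flat$reference_cell_ids <- character(0)
  expect_warning(s0 <- call_subclones(flat), "identical")
  expect_equal(s0$k, 1L)
  expect_true(s0$low_confidence)
})

test_that("profiles without planted structure are flagged low-confidence", {
  set.seed(10)
  noise <- default_cnv()$cnv
  noise$values <- matrix(1 + rnorm(60 * 40, sd = 0.05), 60, 40,
                         dimnames = list(paste0("g", 1:60),
                                         paste0("c", 1:40)))
  noise$reference_cell_ids <- character(0)
  sr <- call_subclones(noise)
  expect_true(sr$low_confidence)
})

test_that("malignancy classification is near-perfect and guards references", {
  cx <- default_cohort(); dn <- default_cnv()
  cl <- setNames(cx$truth$true_type, cx$truth$cell_id)
  mc <- classify_malignancy(dn$levels, cl[names(dn$levels)], dn$ref)
  acc <- mean(mc$malignant[cx$truth$cell_id] == cx$truth$true_malignant)
  expect_gte(acc, 0.98)
  expect_false(any(mc$malignant[dn$ref]))
  expect_false(mc$unreliable)
  # all-normal input walks the unimodal warning path
  set.seed(2)
  lv0 <- setNames(abs(rnorm(200, 1, 0.1)), paste0("c", 1:200))
  cl0 <- setNames(rep(c("a", "b"), 100), names(lv0))
  expect_warning(m0 <- classify_malignancy(lv0, cl0), "unimodal")
  expect_true(m0$unreliable)
})

test_that("differential CNV pinpoints the subclone-specific segments", {
  cx <- default_cohort(); dn <- default_cnv()
  tc <- cx$truth
  s1 <- tc$cell_id[tc$true_malignant & tc$true_subclone == "subclone1"]
  s2 <- tc$cell_id[tc$true_malignant & tc$true_subclone == "subclone2"]
  tab <- differential_cnv(dn$cnv, s1, s2)
  # at ~500 cells per group minute systematic differences reach q < 0.05;
  # the planted events are the rows that are both significant and large
  sig <- tab[tab$significant & abs(tab$delta_mean) > 0.1, ]
  seg_genes <- dn$cnv$genes$gene_id[dn$cnv$genes$chrom %in%
                                      c("chr1", "chr2")]
  expect_gt(nrow(sig), 100)
  expect_gte(mean(sig$gene_id %in% seg_genes), 0.95)
  # the gained segment has positive delta, the lost one negative
  chr1_sig <- sig[sig$gene_id %in%
                    dn$cnv$genes$gene_id[dn$cnv$genes$chrom == "chr1"], ]
  expect_true(all(chr1_sig$delta_mean > 0))
  # identical groups: all deltas zero, no significance
  same <- differential_cnv(dn$cnv, s1[1:5], s1[1:5])
  expect_true(all(same$delta_mean == 0))
  expect_true(all(!same$significant))
  expect_error(differential_cnv(dn$cnv, s1[1:2], s2), "at least 3")
})

test_that("differential CNV p-values come from the exact enumeration path", {
  dn <- default_cnv()
  cells <- colnames(dn$cnv$values)[1:8]
  tab <- differential_cnv(dn$cnv, cells[1:4], cells[5:8])
  g <- tab$gene_id[1]
  i <- match(g, dn$cnv$genes$gene_id)
  expect_equal(tab$p_value[tab$gene_id == g],
               mw_enum_oracle(dn$cnv$values[i, cells[1:4]],
                              dn$cnv$values[i, cells[5:8]]))
})
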