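# small fast configuration used where the full cohort is unnecessary
small_config <- function(seed = 5L, ...) {
  sim_config(
    n_cells_per_type = c("NSC-like" = 60, "EpC-like" = 60, "OPC" = 60),
    gradient_types = c("NSC-like", "EpC-like"),
    n_chromosomes = 4, genes_per_chromosome = 120,
    cnv_segments = list(
      list(subclone = "subclone1", chrom = "chr1", start = 1, end = 120,
           factor = 1.5)),
    n_samples = 2, condition_per_sample = c("primary", "recurrent"),
    rng_seed = seed, ...)
}

test_that("config invariants are enforced", {
  expect_error(small_config(subclone_fractions = c(subclone1 = 0.6,
                                                   subclone2 = 0.3)),
               "sum to 1")
  expect_error(sim_config(cnv_segments = list(
    list(subclone = "subclone1", chrom = "chr1", start = 10, end = 900,
         factor = 1.5))), "outside its chromosome")
  expect_error(sim_config(cnv_segments = list(
    list(subclone = "subclone1", chrom = "chr1", start = 1, end = 10,
         factor = -1))), "positive")
  expect_error(sim_config(nb_dispersion = 0), "positive")
})

test_that("identical seeds give identical cohorts", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(as.matrix(a$counts$values), as.matrix(b$counts$values))
  expect_identical(a$truth$samples, b$truth$samples)
})

test_that("planted copy factor is recovered in raw group means", {
  cx <- default_cohort()
  tc <- cx$co$truth$cells
  chr1 <- cx$co$genes$gene_id[cx$co$genes$chrom == "chr1"]
  s1 <- tc$cell_id[tc$true_malignant & tc$true_subclone == "subclone1"]
  s2 <- tc$cell_id[tc$true_malignant & tc$true_subclone == "subclone2"]
  expect_gte(length(s1), 200); expect_gte(length(s2), 200)
  v <- cx$co$counts$values
  grp_mean <- function(g, cc) sum(v[g, cc]) / (length(g) * length(cc))
  ratio <- grp_mean(chr1, s1) / grp_mean(chr1, s2)
  expect_gt(ratio, 1.5 * 0.95)
  expect_lt(ratio, 1.5 * 1.05)
  # subclones are exchangeable where no factor differs (chr3 carries none)
  chr3 <- cx$co$genes$gene_id[cx$co$genes$chrom == "chr3"]
  ratio0 <- grp_mean(chr3, s1) / grp_mean(chr3, s2)
  expect_gt(ratio0, 0.95); expect_lt(ratio0, 1.05)
})

test_that("mito fraction, gene-count gradient and survival link are planted", {
  cx <- default_cohort()
  v <- cx$co$counts$values
  mito <- grepl("^MT-", cx$co$counts$gene_ids)
  mf <- Matrix::colSums(v[mito, ]) / Matrix::colSums(v)
  expect_lt(abs(mean(mf) - 0.05), 0.01)
  tc <- cx$co$truth$cells
  g <- Matrix::colSums(v > 0)
  rho <- cor(g[match(tc$cell_id[tc$true_malignant], colnames(v))],
             tc$true_pseudotime[tc$true_malignant], method = "spearman")
  expect_lte(rho, -0.5)
  # non-malignant cells carry no subclone label
  expect_true(all(is.na(tc$true_subclone[!tc$true_malignant])))
  expect_false(anyDuplicated(tc$cell_id) > 0)
  # stem-rich samples die faster
  s <- cx$co$truth$samples
  hi <- s$true_stemness > mean(s$true_stemness)
  expect_lt(mean(s$survival_time[hi]), mean(s$survival_time[!hi]))
})

test_that("10x MTX write/read round trip is lossless", {
  co <- generate_cohort(small_config())
  for (gz in c(FALSE, TRUE)) {
    d <- withr::local_tempdir()
    write_10x_mtx(co$counts, co$genes, dir = d, gzip = gz)
    back <- read_counts_mtx(d)
    expect_identical(as.matrix(back$values), as.matrix(co$counts$values))
    expect_identical(back$gene_ids, co$counts$gene_ids)
    expect_identical(back$cell_ids, co$counts$cell_ids)
  }
})

test_that("MTX writer handles degenerate matrices and declares dimensions", {
  d <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(1, 0, 2, 0, 3, 4), nrow = 3), sparse = TRUE)
  em <- expr_matrix(m, c("a", "b", "c"), c("x", "y"), "counts")
  write_10x_mtx(em, dir = d)
  header <- readLines(file.path(d, "matrix.mtx"), n = 2)
  expect_identical(header[2], "3 2 4")
  # zero-cell matrix
  d2 <- withr::local_tempdir()
  em0 <- expr_matrix(m[, integer(0), drop = FALSE], c("a", "b", "c"),
                     character(0), "counts")
  write_10x_mtx(em0, dir = d2)
  expect_identical(readLines(file.path(d2, "matrix.mtx"))[2], "3 0 0")
  expect_equal(dim(read_counts_mtx(d2)), c(3L, 0L))
})

test_that("reader rejects inconsistent inputs", {
  d <- withr::local_tempdir()
  co <- generate_cohort(small_config())
  write_10x_mtx(co$counts, co$genes, dir = d)
  bad <- readLines(file.path(d, "barcodes.tsv"))
  bad[2] <- bad[1]
  writeLines(bad, file.path(d, "barcodes.tsv"))
  expect_error(read_counts_mtx(d), "duplicate")
  writeLines(bad[-1], file.path(d, "barcodes.tsv"))
  expect_error(read_counts_mtx(d), "disagree")
})
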