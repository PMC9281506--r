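#' Read a 10x-style MatrixMarket count directory
#'
#' Expects `matrix.mtx`, a gene table (`genes.tsv` or `features.tsv`,
#' first column = gene id) and `barcodes.tsv`, each optionally gzipped.
#'
#' @param dir directory containing the triplet files.
#' @return an [expr_matrix] with layer `"counts"` (genes x cells).
#' @export
read_counts_mtx <- function(dir) {
  find_one <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    stop("missing ", stems[1], " (or .gz) in ", dir)
  }
  mtx <- find_one("matrix.mtx")
  genes <- find_one(c("genes.tsv", "features.tsv"))
  barcodes <- find_one("barcodes.tsv")
  m <- Matrix::readMM(mtx)
  gt <- utils::read.table(genes, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  bc <- readLines(barcodes)
  if (nrow(gt) != nrow(m) || length(bc) != ncol(m))
    stop("matrix dimensions disagree with gene/barcode tables")
  if (anyDuplicated(gt[[1]])) stop("duplicate gene ids in gene table")
  if (anyDuplicated(bc)) stop("duplicate cell barcodes")
  if (length(m@x) && (min(m@x) < 0 || any(m@x != floor(m@x))))
    stop("count matrix contains negative or non-integer values")
  expr_matrix(methods::as(m, "CsparseMatrix"), gt[[1]], bc, "counts")
}

# mitochondrial genes by the community "MT-" prefix convention
is_mito_gene <- function(gene_ids) grepl("^mt-", gene_ids, ignore.case = TRUE)

#' Quality-control filter on a count matrix
#'
#' Cells are removed when they have strictly fewer than `min_genes`
#' distinct expressed genes, or when mitochondrial (MT- prefixed) reads
#' take up strictly more than `max_mito_frac` of their total. Genes are
#' then kept only if expressed (count > 0) in at least `min_cells_per_gene`
#' of the retained cells. Cell filters run first; the gene filter sees only
#' the kept cells — the order changes results and is part of the contract.
#'
#' @param counts [expr_matrix] with layer `"counts"`.
#' @param min_genes minimum distinct expressed genes per cell (kept if
#'   `>= min_genes`).
#' @param max_mito_frac maximum tolerated mitochondrial read fraction
#'   (kept if `<= max_mito_frac`).
#' @param min_cells_per_gene minimum kept cells a gene must appear in.
#' @return list(counts = filtered [expr_matrix], report = QC report list
#'   with fields n_cells_in, n_cells_kept, n_removed_mito,
#'   n_removed_genes_per_cell, n_genes_in, n_genes_kept).
#' @export
qc_filter <- function(counts, min_genes = 1500, max_mito_frac = 0.12,
                      min_cells_per_gene = 10) {
  stopifnot(inherits(counts, "expr_matrix"), counts$layer == "counts")
  v <- counts$values
  genes_per_cell <- Matrix::colSums(v > 0)
  mito <- is_mito_gene(counts$gene_ids)
  tot <- Matrix::colSums(v)
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::colSums(v[mito, , drop = FALSE])) / pmax(tot, 1)
  } else rep(0, ncol(v))
  fail_genes <- genes_per_cell < min_genes
  fail_mito <- mito_frac > max_mito_frac
  keep_cells <- !(fail_genes | fail_mito)
  if (!any(keep_cells)) stop("empty after QC: all cells removed")
  vk <- v[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(vk > 0) >= min_cells_per_gene
  report <- list(
    n_cells_in = ncol(v),
    n_cells_kept = sum(keep_cells),
    n_removed_mito = sum(fail_mito),
    n_removed_genes_per_cell = sum(fail_genes),
    n_genes_in = nrow(v),
    n_genes_kept = sum(keep_genes))
  out <- expr_matrix(vk[keep_genes, , drop = FALSE],
                     counts$gene_ids[keep_genes],
                     counts$cell_ids[keep_cells], "counts")
  list(counts = out, report = report)
}

#' Log-normalize counts to the E layer
#'
#' `E = log2(1 + CPM/10)` with `CPM = count / cell total x 1e6`. Counts
#' per million stand in for TPM since UMI data carries no gene-length bias.
#'
#' @param counts [expr_matrix], layer `"counts"`.
#' @return [expr_matrix] with layer `"E"` (dense).
#' @export
normalize_E <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"), counts$layer == "counts")
  tot <- Matrix::colSums(counts$values)
  if (any(tot == 0)) stop("cells with zero total counts cannot be normalized")
  cpm <- sweep(dense_values(counts), 2, as.numeric(tot), `/`) * 1e6
  expr_matrix(log2(1 + cpm / 10), counts$gene_ids, counts$cell_ids, "E")
}

#' Gene-centered relative expression (Er layer)
#'
#' Subtracts each gene's mean across cells; every gene then averages to 0.
#'
#' @param E [expr_matrix], layer `"E"` (or `"Er"`; centering is idempotent).
#' @return [expr_matrix] with layer `"Er"`.
#' @export
relative_Er <- function(E) {
  stopifnot(inherits(E, "expr_matrix"), E$layer %in% c("E", "Er"))
  v <- dense_values(E)
  expr_matrix(v - rowMeans(v), E$gene_ids, E$cell_ids, "Er")
}

#' Highly-variable-gene selection, PCA and graph clustering
#'
#' Selects `n_hvg` genes by mean-binned normalized dispersion of E,
#' z-scales them, projects onto the top `n_pcs` principal components, and
#' partitions cells with Louvain community detection on a shared
#' nearest-neighbor graph. Deterministic under the supplied seed.
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param n_hvg number of highly variable genes (clamped to the gene count).
#' @param n_pcs number of principal components (reduced with a warning when
#'   fewer cells are available).
#' @param k_nn neighbors for the SNN graph.
#' @param resolution Louvain resolution.
#' @param rng_seed integer seed.
#' @return integer cluster label per cell (named by cell id).
#' @export
preprocess_cluster <- function(E, n_hvg = 5000, n_pcs = 50, k_nn = 20,
                               resolution = 1, rng_seed = 0L) {
  stopifnot(inherits(E, "expr_matrix"), E$layer == "E")
  v <- dense_values(E)
  ng <- nrow(v); nc <- ncol(v)
  if (n_pcs >= nc) {
    warning("fewer cells than requested PCs; reducing n_pcs")
    n_pcs <- max(1L, nc - 1L)
  }
  hvg <- select_hvg(v, min(n_hvg, ng))
  x <- v[hvg, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  z <- t(scale(t(x)))        # cells stay columns
  z[z > 10] <- 10; z[z < -10] <- -10
  n_pcs <- min(n_pcs, nrow(z) - 1L, nc - 1L)
  pcs <- stats::prcomp(t(z), center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  g <- snn_graph(pcs, k = min(k_nn, nc - 1L))
  comm <- with_seed(rng_seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  stats::setNames(as.integer(igraph::membership(comm)), E$cell_ids)
}

# dispersion-based HVG ranking (variance/mean, z-scored within 20 mean bins)
select_hvg <- function(v, n) {
  mu <- rowMeans(v)
  va <- apply(v, 1, stats::var)
  disp <- ifelse(mu > 0, va / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = 20, labels = FALSE)
  zd <- stats::ave(disp, bins, FUN = function(d) {
    s <- stats::sd(d)
    if (is.na(s) || s == 0) return(rep(0, length(d)))
    (d - mean(d)) / s
  })
  order(zd, decreasing = TRUE)[seq_len(n)]
}

# shared-nearest-neighbor graph with Jaccard edge weights
snn_graph <- function(pcs, k) {
  n <- nrow(pcs)
  d <- as.matrix(stats::dist(pcs))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) adj[i, nn[i, ]] <- 1L
  shared <- adj %*% t(adj)
  deg <- rowSums(adj)
  un <- outer(deg, deg, `+`) - shared
  w <- shared / pmax(un, 1)
  w[w < 1 / 15] <- 0
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "max", weighted = TRUE)
}
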