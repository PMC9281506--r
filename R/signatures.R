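#' Construct a named signature gene set
#'
#' @param name cell-type label.
#' @param genes character vector of gene ids (non-empty, duplicates
#'   removed).
#' @return list of class `signature_set` with fields `name`, `genes`.
#' @export
signature_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("signature '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "signature_set")
}

#' Read signature sets from a two-column TSV (set name, gene id)
#'
#' @param path TSV file, no header.
#' @return named list of [signature_set] objects.
#' @export
read_signatures <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  sets <- split(tab[[2]], tab[[1]])
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) signature_set(nm, sets[[nm]]))
}

#' One-vs-rest marker detection per group
#'
#' For every group with at least three cells, each gene passing the
#' detection and fold-change prefilters is tested one-vs-rest with a
#' two-sided tie-aware Mann-Whitney test; p-values are BH-adjusted within
#' each group's tested set. Log fold change is the difference of group
#' means of E (E is log2-scaled, so the difference reads as a log2 ratio).
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param labels group label per cell.
#' @param min_pct minimum detection fraction in either population.
#' @param min_logfc minimum absolute mean-E difference.
#' @param alpha marker significance level on q.
#' @return data.frame with columns gene_id, group, log_fold_change,
#'   p_value, q_value, pct_in_group, pct_out_group, marker (q < alpha and
#'   positive fold change).
#' @export
find_markers <- function(E, labels, min_pct = 0.1, min_logfc = 0.25,
                         alpha = 0.05) {
  stopifnot(inherits(E, "expr_matrix"))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(E$cell_ids))
  sizes <- table(labels)
  if (sum(sizes >= 3) < 2)
    stop("need at least two groups with >= 3 cells")
  v <- dense_values(E)
  n <- ncol(v)
  ranks <- t(apply(v, 1, rank))
  small <- n <= 30 && all(choose(n, sizes) <= 20000)
  res <- list()
  for (g in names(sizes)) {
    if (sizes[[g]] < 3) {
      warning("group '", g, "' has fewer than 3 cells; skipped")
      next
    }
    ing <- labels == g
    pct_in <- rowMeans(v[, ing, drop = FALSE] > 0)
    pct_out <- rowMeans(v[, !ing, drop = FALSE] > 0)
    lfc <- rowMeans(v[, ing, drop = FALSE]) -
      rowMeans(v[, !ing, drop = FALSE])
    tested <- (pct_in >= min_pct | pct_out >= min_pct) &
      abs(lfc) >= min_logfc
    if (!any(tested)) next
    if (small) {
      p <- vapply(which(tested), function(i) {
        mann_whitney(v[i, ing], v[i, !ing])$p_value
      }, 0)
    } else {
      p <- mw_rows(v[tested, , drop = FALSE], ing,
                   ranks[tested, , drop = FALSE])$p
    }
    q <- stats::p.adjust(p, method = "BH")
    res[[g]] <- data.frame(
      gene_id = E$gene_ids[tested], group = g,
      log_fold_change = lfc[tested], p_value = p, q_value = q,
      pct_in_group = pct_in[tested], pct_out_group = pct_out[tested],
      marker = q < alpha & lfc[tested] > 0,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Gene-module score with expression-binned control genes
#'
#' Genes are binned into `n_bins` equal-frequency bins of their average
#' expression across cells; for each signature gene, `n_ctrl_per_gene`
#' control genes are drawn from its bin (with replacement when the bin is
#' smaller than the request). The per-cell score is the mean E over
#' signature genes minus the mean E over all drawn control genes, so a
#' random gene set scores near zero by construction.
#'
#' @param E [expr_matrix], layer `"E"` (or `"Er"`).
#' @param signature a [signature_set] (or plain character vector of genes).
#' @param n_bins number of average-expression bins.
#' @param n_ctrl_per_gene control genes drawn per signature gene.
#' @param rng_seed integer seed for the control draw.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(E, signature, n_bins = 25, n_ctrl_per_gene = 100,
                         rng_seed = 0L) {
  stopifnot(inherits(E, "expr_matrix"))
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else unique(as.character(signature))
  present <- genes %in% E$gene_ids
  if (!any(present)) stop("no signature gene present in the matrix")
  if (!all(present))
    warning(sum(!present), " signature gene(s) absent; dropped")
  genes <- genes[present]
  v <- dense_values(E)
  avg <- rowMeans(v)
  n_bins <- max(1L, min(n_bins, nrow(v)))
  bin <- if (n_bins == 1L) rep(1L, nrow(v)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  sig_idx <- match(genes, E$gene_ids)
  ctrl_idx <- with_seed(derive_seed(rng_seed, "module_score"), {
    unlist(lapply(sig_idx, function(i) {
      pool <- which(bin == bin[i])
      sample(pool, n_ctrl_per_gene,
             replace = length(pool) < n_ctrl_per_gene)
    }))
  })
  sig_mean <- colMeans(v[sig_idx, , drop = FALSE])
  ctrl_mean <- colMeans(v[ctrl_idx, , drop = FALSE])
  stats::setNames(sig_mean - ctrl_mean, E$cell_ids)
}

#' Signature-enrichment (SE) cell-type classification of clusters
#'
#' Scores every signature on every cell with [module_score()], averages
#' scores within clusters, and assigns each cluster the cell type with the
#' highest mean score. Ties are broken by signature input order with a
#' warning.
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param clusters cluster label per cell.
#' @param signatures named list of [signature_set]s (or gene vectors).
#' @param n_bins,n_ctrl_per_gene,rng_seed passed to [module_score()].
#' @return list(assignment = named character cluster -> type,
#'   cluster_scores = cluster x type matrix, cell_scores = cell x type
#'   matrix).
#' @export
se_classify <- function(E, clusters, signatures, n_bins = 25,
                        n_ctrl_per_gene = 100, rng_seed = 0L) {
  stopifnot(length(clusters) == length(E$cell_ids))
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, function(s)
      if (inherits(s, "signature_set")) s$name else stop("unnamed signature"),
      "")
  cell_scores <- vapply(signatures, function(sig)
    module_score(E, sig, n_bins, n_ctrl_per_gene, rng_seed),
    numeric(length(E$cell_ids)))
  cl <- as.character(clusters)
  cluster_scores <- apply(cell_scores, 2, function(s) {
    tapply(s, cl, mean)
  })
  cluster_scores <- matrix(cluster_scores,
                           nrow = length(unique(cl)),
                           dimnames = list(sort(unique(cl)),
                                           names(signatures)))
  assignment <- apply(cluster_scores, 1, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1)
      warning("signature-score tie; first-listed type taken")
    names(signatures)[top[1]]
  })
  list(assignment = assignment, cluster_scores = cluster_scores,
       cell_scores = cell_scores)
}

#' Reverse signature-enrichment (rSE) classification against a reference
#'
#' Extracts markers of every query cluster with [find_markers()], scores
#' each marker set on a typed reference with [module_score()], and assigns
#' the reference type with the highest mean score. When an SE result is
#' supplied, call concordance and the Pearson correlation of the two
#' cluster-by-type score tables are reported.
#'
#' @param query_E,query_clusters query expression (layer `"E"`) and
#'   cluster labels.
#' @param reference_E,reference_types typed reference expression and
#'   per-cell type labels.
#' @param n_top maximum markers per cluster.
#' @param se_result optional output of [se_classify()] on the query.
#' @param n_bins,n_ctrl_per_gene,rng_seed passed to [module_score()].
#' @return list(assignment, cluster_scores, unassigned = clusters without
#'   markers, agreement = list(concordance, score_correlation) or NULL).
#' @export
rse_classify <- function(query_E, query_clusters, reference_E,
                         reference_types, n_top = 50, se_result = NULL,
                         n_bins = 25, n_ctrl_per_gene = 100,
                         rng_seed = 0L) {
  mk <- find_markers(query_E, query_clusters)
  ref_types <- sort(unique(as.character(reference_types)))
  cl_levels <- sort(unique(as.character(query_clusters)))
  scores <- matrix(NA_real_, length(cl_levels), length(ref_types),
                   dimnames = list(cl_levels, ref_types))
  assignment <- stats::setNames(rep(NA_character_, length(cl_levels)),
                                cl_levels)
  unassigned <- character(0)
  for (cl in cl_levels) {
    sub <- mk[mk$group == cl & mk$marker, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0) {
      warning("query cluster '", cl, "' has no markers; unassigned")
      unassigned <- c(unassigned, cl)
      next
    }
    sub <- sub[order(sub$p_value, -sub$log_fold_change), , drop = FALSE]
    genes <- utils::head(sub$gene_id, n_top)
    genes <- genes[genes %in% reference_E$gene_ids]
    if (length(genes) == 0) {
      unassigned <- c(unassigned, cl); next
    }
    sc <- module_score(reference_E, genes, n_bins, n_ctrl_per_gene,
                       rng_seed)
    scores[cl, ] <- tapply(sc, as.character(reference_types),
                           mean)[ref_types]
    assignment[cl] <- ref_types[which.max(scores[cl, ])]
  }
  agreement <- NULL
  if (!is.null(se_result)) {
    common <- intersect(names(assignment)[!is.na(assignment)],
                        names(se_result$assignment))
    conc <- mean(assignment[common] == se_result$assignment[common])
    shared_types <- intersect(colnames(scores),
                              colnames(se_result$cluster_scores))
    a <- as.numeric(scores[common, shared_types])
    b <- as.numeric(se_result$cluster_scores[common, shared_types])
    agreement <- list(concordance = conc,
                      score_correlation = stats::cor(a, b))
  }
  list(assignment = assignment, cluster_scores = scores,
       unassigned = unassigned, agreement = agreement)
}

#' Gene-count-based differentiation (undifferentiated) score
#'
#' A simplified differentiation-potential score built on the observation
#' that less differentiated cells express more distinct genes: per-cell
#' expressed-gene counts are correlated with every gene's expression, the
#' `n_top_genes` most count-correlated genes are averaged per cell,
#' optionally k-NN smoothed, and the result is rank-normalized to [0, 1]
#' (1 = least differentiated). This is a deliberately simple stand-in for
#' full differentiation-potential frameworks.
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param n_top_genes genes kept in the count-correlated panel.
#' @param knn_smooth neighbors for score smoothing (0 = none).
#' @return named per-cell score in [0, 1].
#' @export
undiff_score <- function(E, n_top_genes = 200, knn_smooth = 0) {
  stopifnot(inherits(E, "expr_matrix"))
  v <- dense_values(E)
  if (nrow(v) < n_top_genes)
    n_top_genes <- nrow(v)
  g <- colSums(v > 0)
  if (stats::sd(g) == 0) {
    warning("expressed-gene count constant; falling back to its rank")
    return(stats::setNames(rep(0.5, ncol(v)), E$cell_ids))
  }
  cors <- suppressWarnings(as.numeric(stats::cor(t(v), g)))
  cors[is.na(cors)] <- -Inf
  top <- order(cors, decreasing = TRUE)[seq_len(n_top_genes)]
  raw <- colMeans(v[top, , drop = FALSE])
  if (knn_smooth > 0 && ncol(v) > knn_smooth) {
    d <- as.matrix(stats::dist(t(v[top, , drop = FALSE])))
    raw <- vapply(seq_len(ncol(v)), function(i) {
      nb <- order(d[i, ])[seq_len(knn_smooth + 1L)]
      mean(raw[nb])
    }, 0)
  }
  r <- rank(raw, ties.method = "average")
  stats::setNames((r - 1) / (length(r) - 1), E$cell_ids)
}
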