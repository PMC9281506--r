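#' Sample a fixed-size reference cell set of one cell type
#'
#' Non-malignant cells of a single type (e.g. OPCs) serve as the
#' copy-neutral reference the CNV inference is centered on.
#'
#' @param cell_meta data.frame with `cell_id` and `cell_type` columns.
#' @param cell_type type to draw from.
#' @param n reference size; if fewer cells exist, all are returned with a
#'   warning.
#' @param rng_seed integer seed.
#' @return character vector of reference cell ids.
#' @export
sample_reference <- function(cell_meta, cell_type, n = 300, rng_seed = 0L) {
  ids <- cell_meta$cell_id[!is.na(cell_meta$cell_type) &
                             cell_meta$cell_type == cell_type]
  if (length(ids) == 0) stop("no cells of type '", cell_type, "'")
  if (length(ids) <= n) {
    if (length(ids) < n)
      warning("only ", length(ids), " cells of type '", cell_type,
              "' available; using all")
    return(ids)
  }
  with_seed(derive_seed(rng_seed, "reference"), sample(ids, n))
}

#' Expression-inferred copy-number matrix
#'
#' Infers per-gene, per-cell copy-number proxies from log expression:
#' genes are filtered for expression, ordered along the genome, centered
#' on the reference cells, clipped, smoothed with a centered moving
#' average within each chromosome, cell-median centered, re-centered on
#' the reference, and finally mapped onto a 0-2 copy scale (1 = normal
#' copy) by an exponential transform whose linear scale is anchored so the
#' reference cells' 1st-99th percentile spans log2(0.5)..log2(1.5).
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param gene_annotation data.frame (gene_id, chrom, start, ...).
#' @param reference_ids cell ids of the copy-neutral reference (must be
#'   columns of `E`).
#' @param window odd moving-average window (genes).
#' @param expr_cutoff minimum mean E across cells for a gene to enter.
#' @param min_cells_per_gene minimum cells a gene must be expressed in.
#' @param clip symmetric clip applied to centered expression before
#'   smoothing.
#' @param denoise_sd residuals within this many reference standard
#'   deviations of 0 are soft-thresholded away before the copy mapping
#'   (0 disables denoising).
#' @param counts optional counts [expr_matrix]; when given, cells whose
#'   totals fall outside `min_max_counts_per_cell` are dropped before
#'   inference (this filter applies to CNV inference only).
#' @param min_max_counts_per_cell numeric length-2 bounds on cell totals.
#' @return object of class `cnv_matrix`: list(values = gene x cell copy
#'   proxies in [0, 2], genes = ordered annotation used,
#'   reference_cell_ids, window).
#' @export
infer_cnv <- function(E, gene_annotation, reference_ids, window = 101,
                      expr_cutoff = 0.1, min_cells_per_gene = 5,
                      clip = 3.0, denoise_sd = 1.0, counts = NULL,
                      min_max_counts_per_cell = c(5e2, 6e6)) {
  stopifnot(inherits(E, "expr_matrix"), E$layer == "E")
  if (window %% 2 == 0) stop("window must be odd")
  if (!all(reference_ids %in% E$cell_ids))
    stop("reference ids missing from the matrix")
  keep_cells <- E$cell_ids
  if (!is.null(counts)) {
    tot <- Matrix::colSums(counts$values)[keep_cells]
    keep_cells <- keep_cells[tot >= min_max_counts_per_cell[1] &
                               tot <= min_max_counts_per_cell[2]]
    reference_ids <- intersect(reference_ids, keep_cells)
  }
  ann <- gene_annotation[gene_annotation$gene_id %in% E$gene_ids, ,
                         drop = FALSE]
  chrom_order <- unique(ann$chrom)
  ann <- ann[order(match(ann$chrom, chrom_order), ann$start), ,
             drop = FALSE]
  v <- dense_values(E)[ann$gene_id, keep_cells, drop = FALSE]
  expressed <- rowSums(v > 0)
  keep <- rowMeans(v) >= expr_cutoff & expressed >= min_cells_per_gene
  ann <- ann[keep, , drop = FALSE]
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) stop("no genes left after expression filtering")
  ref_cols <- match(reference_ids, colnames(v))

  # (3) reference centering, (4) clipping
  v <- v - rowMeans(v[, ref_cols, drop = FALSE])
  v[v > clip] <- clip; v[v < -clip] <- -clip
  # (5) within-chromosome moving average
  for (ch in unique(ann$chrom)) {
    rows <- which(ann$chrom == ch)
    if (length(rows) < 3) {
      warning("chromosome ", ch, " has fewer than 3 genes; not smoothed")
      next
    }
    v[rows, ] <- running_mean_rows(v[rows, , drop = FALSE], window)
  }
  # (6) cell-median centering, (7) residual reference centering
  v <- sweep(v, 2, apply(v, 2, stats::median))
  v <- v - rowMeans(v[, ref_cols, drop = FALSE])
  # (8) 0-2 copy mapping anchored on the reference spread. The linear
  # scale is fixed before denoising so the reference 1st-99th percentile
  # spans one copy (log2 0.5 .. log2 1.5); residuals inside the reference
  # noise band are then soft-thresholded away (standard expression-CNV
  # denoising) and the remainder mapped through 2^x onto [0, 2].
  qs <- stats::quantile(v[, ref_cols], c(0.01, 0.99), names = FALSE)
  span <- qs[2] - qs[1]
  s <- if (span > 0) (log2(1.5) - log2(0.5)) / span else 1
  if (denoise_sd > 0) {
    lambda <- denoise_sd * stats::sd(v[, ref_cols])
    v <- sign(v) * pmax(abs(v) - lambda, 0)
  }
  cm <- pmin(pmax(2^(v * s), 0), 2)
  structure(list(values = cm, genes = ann,
                 reference_cell_ids = reference_ids, window = window),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf(
    "<cnv_matrix> %d genes x %d cells (window %d, %d reference cells)\n",
    nrow(x$values), ncol(x$values), x$window,
    length(x$reference_cell_ids)))
  invisible(x)
}

#' Per-cell CNV level (quadratic sum over expressed genes)
#'
#' Copy proxies are re-standardized to -1..1 (`s = c - 1`) and each cell's
#' level is the sum of `s^2` over the genes that cell expresses (raw
#' count > 0). A copy-neutral cell scores exactly 0.
#'
#' @param cnv a [infer_cnv()] result.
#' @param counts counts [expr_matrix] supplying the expressed-gene mask;
#'   if omitted every gene counts.
#' @return named numeric vector, one non-negative level per cell.
#' @export
cnv_level <- function(cnv, counts = NULL) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  s2 <- (cnv$values - 1)^2
  if (!is.null(counts)) {
    mask <- as.matrix(
      counts$values[cnv$genes$gene_id, colnames(cnv$values),
                    drop = FALSE] > 0)
    s2 <- s2 * mask
  }
  colSums(s2)
}

#' Ward-linkage subclone calling on CNV profiles
#'
#' Hierarchical clustering (ward.D2) of cells on Euclidean distances
#' between their copy-proxy profiles; the number of subclones is chosen by
#' maximal mean silhouette over `k_range` unless fixed.
#'
#' @param cnv a [infer_cnv()] result.
#' @param cells cell ids to cluster (default: all non-reference cells).
#' @param k fixed subclone count, or `"auto"`.
#' @param k_range candidate k values for the silhouette search.
#' @return list of class `subclone_result`: labels (named
#'   "subclone1"... per cell), k, silhouette (mean width, NA for fixed
#'   k = 1), merge heights, low_confidence flag.
#' @export
call_subclones <- function(cnv, cells = NULL, k = "auto", k_range = 2:6) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  if (is.null(cells))
    cells <- setdiff(colnames(cnv$values), cnv$reference_cell_ids)
  x <- t(cnv$values[, cells, drop = FALSE])
  d <- stats::dist(x)
  if (max(d) == 0) {
    warning("all CNV profiles identical; single cluster returned")
    return(structure(list(
      labels = stats::setNames(rep("subclone1", length(cells)), cells),
      k = 1L, silhouette = NA_real_, merge_heights = numeric(0),
      low_confidence = TRUE), class = "subclone_result"))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- NA_real_
  if (identical(k, "auto")) {
    k_range <- k_range[k_range < length(cells)]
    widths <- vapply(k_range, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, 3])
    }, 0)
    k <- k_range[which.max(widths)]
    sil <- max(widths)
  } else if (k > 1) {
    sil <- mean(cluster::silhouette(stats::cutree(hc, k), d)[, 3])
  }
  lab <- stats::cutree(hc, k)
  # stable naming: subclone1 = largest
  sizes <- sort(table(lab), decreasing = TRUE)
  remap <- stats::setNames(paste0("subclone", seq_along(sizes)),
                           names(sizes))
  structure(list(
    labels = stats::setNames(unname(remap[as.character(lab)]), cells),
    k = as.integer(k), silhouette = sil, merge_heights = hc$height,
    low_confidence = is.na(sil) || sil < 0.1),
    class = "subclone_result")
}

#' @export
print.subclone_result <- function(x, ...) {
  cat(sprintf("<subclone_result> k = %d (mean silhouette %.3f%s)\n",
              x$k, x$silhouette,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  print(table(x$labels))
  invisible(x)
}

# Otsu threshold on a 1-D sample (fallback split when the model-based
# mixture is unavailable)
otsu_threshold <- function(x, n_breaks = 256) {
  br <- seq(min(x), max(x), length.out = n_breaks)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), n_breaks - 1)
  p <- h / sum(h)
  w1 <- cumsum(p)
  m <- cumsum(p * br[-n_breaks])
  mt <- m[length(m)]
  between <- (mt * w1 - m)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  br[which.max(between)]
}

#' Malignancy call from CNV levels
#'
#' Thresholds the CNV-level distribution and smooths the per-cell calls
#' by majority vote within each cluster, so a cluster is called
#' malignant as a whole when most of its cells exceed the threshold.
#' With a copy-neutral reference available the threshold is 2.5 times
#' the reference's median level — a cell must carry well over twice the
#' copy-neutral background burden. Without a reference the level
#' distribution is split with a 2-component Gaussian mixture on the log
#' scale (levels are non-negative and right-skewed), with an Otsu
#' threshold as fallback; effectively unimodal levels are flagged
#' unreliable. Reference cells are never called malignant.
#'
#' @param levels named per-cell CNV levels ([cnv_level()]).
#' @param clusters named per-cell cluster labels covering the same
#'   cells; transcriptomic clusters give the most stable votes.
#' @param reference_ids cells forced non-malignant; when at least 20 of
#'   them carry levels they anchor the threshold.
#' @param ref_multiplier threshold as a multiple of the reference median
#'   level.
#' @return list(malignant = named logical, threshold, unreliable flag).
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_malignancy <- function(levels, clusters, reference_ids = NULL,
                                ref_multiplier = 2.5) {
  stopifnot(length(levels) == length(clusters))
  cl <- as.character(clusters)
  unreliable <- FALSE
  ref_in <- intersect(reference_ids, names(levels))
  if (length(ref_in) >= 20) {
    thr <- ref_multiplier * stats::median(levels[ref_in])
  } else {
    ll <- log1p(levels)
    fit <- tryCatch(
      Mclust(ll, G = 1:2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && fit$G == 2 &&
        length(unique(fit$classification)) == 2) {
      hi <- which.max(fit$parameters$mean)
      # split point between the two components, mapped back
      thr <- expm1((max(ll[fit$classification != hi]) +
                      min(ll[fit$classification == hi])) / 2)
    } else {
      unreliable <- TRUE
      warning("CNV levels look unimodal; malignancy threshold unreliable")
      thr <- if (stats::sd(levels) > 0) otsu_threshold(levels)
             else stats::median(levels)
    }
  }
  raw <- levels > thr
  # majority vote inside each cluster removes singleton flips
  vote <- tapply(raw, cl, mean) > 0.5
  mal <- unname(vote[cl])
  names(mal) <- names(levels)
  if (!is.null(reference_ids)) mal[names(mal) %in% reference_ids] <- FALSE
  list(malignant = mal, threshold = thr, unreliable = unreliable)
}

#' Per-gene differential CNV between two cell groups
#'
#' Two-sided Mann-Whitney test on the copy proxies of every gene between
#' groups A and B with BH adjustment; the effect is the difference of
#' group mean proxies. Genes constant in both groups get p = 1.
#'
#' @param cnv a [infer_cnv()] result.
#' @param cells_a,cells_b cell ids of the two groups (>= 3 each).
#' @param alpha significance level on q.
#' @return data.frame (gene_id, delta_mean, p_value, q_value,
#'   significant) ordered by p.
#' @export
differential_cnv <- function(cnv, cells_a, cells_b, alpha = 0.05) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("both groups need at least 3 cells")
  va <- cnv$values[, cells_a, drop = FALSE]
  vb <- cnv$values[, cells_b, drop = FALSE]
  v <- cbind(va, vb)
  ing <- c(rep(TRUE, ncol(va)), rep(FALSE, ncol(vb)))
  n <- ncol(v)
  if (n <= 30 && choose(n, ncol(va)) <= 20000) {
    p <- vapply(seq_len(nrow(v)), function(i)
      mann_whitney(v[i, ing], v[i, !ing])$p_value, 0)
  } else {
    p <- mw_rows(v, ing)$p
  }
  delta <- rowMeans(va) - rowMeans(vb)
  q <- stats::p.adjust(p, "BH")
  out <- data.frame(gene_id = cnv$genes$gene_id, delta_mean = delta,
                    p_value = p, q_value = q,
                    significant = q < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value), ]
}
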