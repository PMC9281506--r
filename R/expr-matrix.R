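#' Gene-by-cell expression matrix with a layer tag
#'
#' Lightweight container used throughout the pipeline. The `layer` tag
#' records which transformation the values carry:
#' \describe{
#'   \item{counts}{raw non-negative integer UMI counts}
#'   \item{E}{log2(1 + CPM/10), the log-normalized expression used for
#'     scoring (CPM stands in for TPM on UMI data, which has no gene-length
#'     bias)}
#'   \item{Er}{gene-centered relative expression, per-gene mean 0}
#' }
#'
#' @param values numeric matrix (genes x cells), dense or `Matrix` sparse.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell barcodes (columns).
#' @param layer one of `"counts"`, `"E"`, `"Er"`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `layer`.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values),
                        layer = c("counts", "E", "Er")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    stop("dimension mismatch between values and gene/cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (layer == "counts") {
    v <- if (methods::is(values, "sparseMatrix")) values@x else values
    if (length(v) && (min(v) < 0 || any(v != floor(v))))
      stop("counts layer must contain non-negative integers")
  }
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  structure(list(values = values, gene_ids = gene_ids,
                 cell_ids = cell_ids, layer = layer),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer '%s'\n",
              length(x$gene_ids), length(x$cell_ids), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or cell ids
#'
#' @param x an `expr_matrix`.
#' @param genes,cells character ids (or NULL to keep all).
#' @return an `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  g <- if (is.null(genes)) x$gene_ids else genes
  cc <- if (is.null(cells)) x$cell_ids else cells
  if (!all(g %in% x$gene_ids)) stop("unknown gene ids in subset")
  if (!all(cc %in% x$cell_ids)) stop("unknown cell ids in subset")
  expr_matrix(x$values[g, cc, drop = FALSE], g, cc, layer = x$layer)
}

# dense numeric copy of the values (scoring code paths want plain matrices)
dense_values <- function(x) {
  v <- x$values
  if (methods::is(v, "sparseMatrix")) v <- as.matrix(v)
  storage.mode(v) <- "double"
  v
}
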