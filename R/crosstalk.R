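#' Read a ligand-receptor pair table
#'
#' Three-column TSV: ligand gene id, receptor gene id, pathway label.
#'
#' @param path TSV file without header.
#' @return data.frame (ligand, receptor, pathway), duplicates removed.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("ligand", "receptor", "pathway")
  tab[!duplicated(tab[, c("ligand", "receptor")]), , drop = FALSE]
}

#' Permutation-based ligand-receptor interaction scoring
#'
#' For every ordered (source, target) cell-type pair and every L-R pair,
#' the interaction score is mean E of the ligand in the source type times
#' mean E of the receptor in the target type (a product-of-means score in
#' the CellPhoneDB tradition). A null distribution is built by shuffling
#' cell-type labels `n_perm` times; p = (1 + #null >= observed) /
#' (n_perm + 1), BH-adjusted across all scored tuples. Pairs whose ligand
#' or receptor is absent from the matrix are retained with score 0 and
#' p = 1, flagged `missing_gene`.
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param cell_types type label per cell.
#' @param pairs data.frame (ligand, receptor[, pathway]).
#' @param n_perm label permutations (>= 100).
#' @param rng_seed integer seed.
#' @return data.frame (source, target, ligand, receptor, pathway, score,
#'   p_value, q_value, missing_gene).
#' @export
lr_score <- function(E, cell_types, pairs, n_perm = 1000, rng_seed = 0L) {
  stopifnot(inherits(E, "expr_matrix"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  ct <- as.character(cell_types)
  stopifnot(length(ct) == length(E$cell_ids))
  types <- sort(unique(ct))
  if (length(types) < 2) stop("need at least two cell types")
  if (is.null(pairs$pathway)) pairs$pathway <- NA_character_
  genes <- unique(c(pairs$ligand, pairs$receptor))
  present <- genes[genes %in% E$gene_ids]
  v <- dense_values(E)[present, , drop = FALSE]

  type_means <- function(labels) {
    ind <- vapply(types, function(t) labels == t,
                  logical(length(labels)))
    sweep(v %*% ind, 2, colSums(ind), `/`)
  }
  obs_means <- type_means(ct)

  grid <- expand.grid(src = types, tgt = types,
                      pair = seq_len(nrow(pairs)),
                      stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]
  rec <- pairs$receptor[grid$pair]
  missing <- !(lig %in% present) | !(rec %in% present)
  score_from <- function(means) {
    s <- numeric(nrow(grid))
    ok <- !missing
    s[ok] <- means[cbind(match(lig[ok], present),
                         match(grid$src[ok], types))] *
             means[cbind(match(rec[ok], present),
                         match(grid$tgt[ok], types))]
    s
  }
  obs <- score_from(as.matrix(obs_means))
  exceed <- integer(nrow(grid))
  with_seed(derive_seed(rng_seed, "lr_score"), {
    for (i in seq_len(n_perm)) {
      pm <- as.matrix(type_means(sample(ct)))
      exceed <- exceed + (score_from(pm) >= obs - 1e-12)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  p[missing] <- 1
  out <- data.frame(source = grid$src, target = grid$tgt,
                    ligand = lig, receptor = rec,
                    pathway = pairs$pathway[grid$pair],
                    score = obs, p_value = p,
                    missing_gene = missing,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Condition-differential expression of ligands and receptors
#'
#' For every ligand/receptor gene and every cell type present in both
#' conditions, tests whether expression is higher in recurrent than in
#' primary cells (one-sided Mann-Whitney on per-cell E), BH-adjusted
#' across all tests. Genes absent from the matrix and cell types present
#' in only one condition are skipped with a warning.
#'
#' @param E [expr_matrix], layer `"E"`.
#' @param cell_types type label per cell.
#' @param conditions `"primary"`/`"recurrent"` label per cell.
#' @param pairs data.frame (ligand, receptor[, pathway]).
#' @param alpha significance level on q.
#' @return data.frame (gene_id, role, cell_type, delta_mean, p_value,
#'   q_value, significant) — delta is recurrent minus primary mean E.
#' @export
lr_condition_differential <- function(E, cell_types, conditions, pairs,
                                      alpha = 0.05) {
  stopifnot(inherits(E, "expr_matrix"))
  ct <- as.character(cell_types)
  cond <- as.character(conditions)
  stopifnot(length(ct) == length(E$cell_ids),
            length(cond) == length(E$cell_ids))
  if (!all(c("primary", "recurrent") %in% cond))
    stop("both conditions must be present")
  roles <- rbind(
    data.frame(gene_id = unique(pairs$ligand), role = "ligand",
               stringsAsFactors = FALSE),
    data.frame(gene_id = unique(pairs$receptor), role = "receptor",
               stringsAsFactors = FALSE))
  absent <- !(roles$gene_id %in% E$gene_ids)
  if (any(absent)) {
    warning(sum(absent), " ligand/receptor gene(s) absent; skipped")
    roles <- roles[!absent, , drop = FALSE]
  }
  v <- dense_values(E)
  res <- list()
  for (t in sort(unique(ct))) {
    rec_idx <- ct == t & cond == "recurrent"
    pri_idx <- ct == t & cond == "primary"
    if (sum(rec_idx) < 3 || sum(pri_idx) < 3) {
      warning("cell type '", t,
              "' lacks cells in one condition; skipped")
      next
    }
    for (i in seq_len(nrow(roles))) {
      g <- roles$gene_id[i]
      x <- v[g, rec_idx]; y <- v[g, pri_idx]
      mw <- mann_whitney(x, y, alternative = "greater")
      res[[length(res) + 1L]] <- data.frame(
        gene_id = g, role = roles$role[i], cell_type = t,
        delta_mean = mean(x) - mean(y), p_value = mw$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) stop("no testable (gene, cell type) combination")
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < alpha
  out[order(out$p_value), ]
}
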