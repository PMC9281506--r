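#' Pipeline configuration
#'
#' Collects the stage parameters and inputs for [run_pipeline()]. Inputs
#' can be given as paths (10x directory, signature TSV, L-R TSV, survival
#' TSV) or as in-memory objects; paths are validated up front so a broken
#' configuration fails before any compute.
#'
#' @param input either a 10x-style directory path or a list with elements
#'   `counts` ([expr_matrix]) and `genes` (annotation data.frame), e.g.
#'   a [generate_cohort()] result.
#' @param cell_meta cell metadata data.frame or TSV path (needs cell_id,
#'   sample_id, condition); defaults to the cohort's own when `input` is a
#'   cohort list.
#' @param signatures named list of gene vectors / [signature_set]s, or a
#'   two-column TSV path.
#' @param lr_pairs data.frame (ligand, receptor, pathway) or TSV path.
#' @param survival data.frame (sample_id, time, event) or TSV path;
#'   optional.
#' @param undiff_markers,diff_markers trajectory endpoint marker sets
#'   (gene vectors); when NULL they are derived from the data by marker
#'   detection on the stem-like endpoint cells of the stem-dominant
#'   subclone vs the differentiated endpoint cells of the other subclone.
#' @param undiff_type,diff_type cell-type labels of the two endpoints.
#' @param reference_type cell type used as the CNV reference.
#' @param reference_n reference sample size.
#' @param min_genes,max_mito_frac,min_cells_per_gene QC parameters.
#' @param n_hvg,n_pcs,cluster_resolution preprocessing parameters.
#' @param cnv_window,cnv_cutoff CNV smoothing window and expression
#'   cutoff.
#' @param subclone_k `"auto"` or fixed integer.
#' @param n_perm crosstalk permutations.
#' @param output_dir optional directory for TSV outputs and the log.
#' @param rng_seed single global seed fanned out to the stage seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, cell_meta = NULL, signatures,
                            lr_pairs = NULL, survival = NULL,
                            undiff_markers = NULL, diff_markers = NULL,
                            undiff_type = "NSC-like",
                            diff_type = "EpC-like",
                            reference_type = "OPC", reference_n = 300,
                            min_genes = 1500, max_mito_frac = 0.12,
                            min_cells_per_gene = 10,
                            n_hvg = 5000, n_pcs = 50,
                            cluster_resolution = 1,
                            cnv_window = 101, cnv_cutoff = 0.1,
                            subclone_k = "auto", n_perm = 200,
                            output_dir = NULL, rng_seed = 0L) {
  if (is.character(input) && !dir.exists(input))
    stop("input directory does not exist: ", input)
  for (p in list(cell_meta, signatures, lr_pairs, survival))
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("configured file does not exist: ", p)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", "clonetraj", paste0(...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: QC -> normalization -> clustering -> SE cell
#' typing -> CNV inference -> malignancy and subclone calling ->
#' trajectory scoring and sample stratification -> composition statistics
#' -> survival comparison -> ligand-receptor crosstalk. Each stage logs
#' its parameters and sizes; identical configurations give identical
#' outputs. When a stage fails, the error names the stage and previously
#' written outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return list with elements qc_report, cell_meta (cluster, cell_type,
#'   subclone and malignant columns filled), se, cnv, cnv_levels,
#'   subclones, malignancy, trajectory, sample_summary, composition,
#'   survival, crosstalk, markers.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(out_dir, "pipeline.log"), "w")
    on.exit(close(log_con), add = TRUE)
  }
  seed <- config$rng_seed
  res <- list()
  stage <- function(name, expr) {
    log_line(log_con, "stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(obj, file) {
    if (!is.null(out_dir))
      utils::write.table(obj, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  ## inputs -----------------------------------------------------------
  if (is.character(config$input)) {
    counts <- stage("read", read_counts_mtx(config$input))
    genes_path <- file.path(config$input, "genes.tsv")
    genes <- utils::read.table(
      if (file.exists(genes_path)) genes_path
      else paste0(genes_path, ".gz"),
      sep = "\t", header = FALSE,
      col.names = c("gene_id", "chrom", "start", "end"),
      stringsAsFactors = FALSE)
  } else {
    counts <- config$input$counts
    genes <- config$input$genes
  }
  cell_meta <- config$cell_meta
  if (is.null(cell_meta) && !is.character(config$input))
    cell_meta <- config$input$cell_meta
  if (is.character(cell_meta))
    cell_meta <- utils::read.table(cell_meta, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  signatures <- config$signatures
  if (is.character(signatures)) signatures <- read_signatures(signatures)
  lr_pairs <- config$lr_pairs
  if (is.character(lr_pairs)) lr_pairs <- read_lr_pairs(lr_pairs)
  surv_tab <- config$survival
  if (is.character(surv_tab))
    surv_tab <- utils::read.table(surv_tab, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)

  ## qc + normalize ----------------------------------------------------
  qc <- stage("qc", qc_filter(counts, config$min_genes,
                              config$max_mito_frac,
                              config$min_cells_per_gene))
  res$qc_report <- qc$report
  log_line(log_con, sprintf("qc kept %d/%d cells, %d/%d genes",
                            qc$report$n_cells_kept, qc$report$n_cells_in,
                            qc$report$n_genes_kept, qc$report$n_genes_in))
  cell_meta <- cell_meta[match(qc$counts$cell_ids, cell_meta$cell_id), ,
                         drop = FALSE]
  E <- stage("normalize", normalize_E(qc$counts))

  ## cluster + cell typing ---------------------------------------------
  cl <- stage("cluster", preprocess_cluster(
    E, config$n_hvg, config$n_pcs,
    resolution = config$cluster_resolution,
    rng_seed = derive_seed(seed, "cluster")))
  cell_meta$cluster <- unname(cl[cell_meta$cell_id])
  se <- stage("annotate", se_classify(
    E, cell_meta$cluster, signatures,
    rng_seed = derive_seed(seed, "se")))
  cell_meta$cell_type <- unname(
    se$assignment[as.character(cell_meta$cluster)])
  res$se <- se

  ## cnv ----------------------------------------------------------------
  ref_ids <- stage("cnv", sample_reference(
    cell_meta, config$reference_type, config$reference_n,
    rng_seed = derive_seed(seed, "reference")))
  cnv <- stage("cnv", infer_cnv(E, genes, ref_ids,
                                window = config$cnv_window,
                                expr_cutoff = config$cnv_cutoff,
                                counts = qc$counts))
  levels <- cnv_level(cnv, qc$counts)
  # malignancy calls are smoothed over the transcriptomic clusters (CNV
  # clusters at k = 2 can lump weak-signal tumor cells with normals)
  expr_cl <- stats::setNames(cell_meta$cluster, cell_meta$cell_id)
  mal <- stage("malignancy", classify_malignancy(
    levels, expr_cl[names(levels)], ref_ids))
  cell_meta$malignant <- unname(mal$malignant[cell_meta$cell_id])
  cell_meta$malignant[cell_meta$cell_id %in% ref_ids] <- FALSE
  mal_cells <- cell_meta$cell_id[!is.na(cell_meta$malignant) &
                                   cell_meta$malignant]
  sub_mal <- stage("subclones",
                   call_subclones(cnv, cells = mal_cells,
                                  k = config$subclone_k))
  cell_meta$subclone <- NA_character_
  cell_meta$subclone[match(mal_cells, cell_meta$cell_id)] <-
    unname(sub_mal$labels[mal_cells])
  res$cnv <- cnv; res$cnv_levels <- levels
  res$subclones <- sub_mal; res$malignancy <- mal

  ## trajectory ----------------------------------------------------------
  undiff_mk <- config$undiff_markers
  diff_mk <- config$diff_markers
  if (is.null(undiff_mk) || is.null(diff_mk)) {
    traj_mk <- stage("trajectory", derive_trajectory_markers(
      E, cell_meta, config$undiff_type, config$diff_type))
    undiff_mk <- undiff_mk %||% traj_mk$undiff
    diff_mk <- diff_mk %||% traj_mk$diff
  }
  traj <- stage("trajectory", trajectory_score(
    E, undiff_mk, diff_mk, rng_seed = derive_seed(seed, "trajectory")))
  summ <- stage("trajectory", summarize_by_sample(traj, cell_meta))
  res$trajectory <- traj; res$sample_summary <- summ

  ## composition statistics ---------------------------------------------
  res$composition <- list()
  if (length(unique(stats::na.omit(cell_meta$subclone))) == 2)
    res$composition$subclone <- stage("stats", composition_contrast(
      cell_meta, "subclone", unit = "cell"))
  if (length(unique(cell_meta$condition)) == 2)
    res$composition$condition <- tryCatch(
      composition_contrast(cell_meta, "condition", unit = "sample"),
      error = function(e) {
        log_line(log_con, "condition contrast skipped: ",
                 conditionMessage(e)); NULL
      })

  ## survival -------------------------------------------------------------
  if (!is.null(surv_tab)) {
    sv <- merge(surv_tab, summ[, c("sample_id", "group")],
                by = "sample_id")
    names(sv)[names(sv) == "survival_time"] <- "time"
    if (length(unique(sv$group)) == 2)
      res$survival <- stage("survival", km_logrank(sv))
  }

  ## crosstalk ------------------------------------------------------------
  if (!is.null(lr_pairs)) {
    res$crosstalk <- list(
      interactions = stage("crosstalk", lr_score(
        E, cell_meta$cell_type, lr_pairs, n_perm = config$n_perm,
        rng_seed = derive_seed(seed, "crosstalk"))),
      condition_differential = if (length(unique(cell_meta$condition)) == 2)
        stage("crosstalk", lr_condition_differential(
          E, cell_meta$cell_type, cell_meta$condition, lr_pairs)))
  }

  res$cell_meta <- cell_meta
  ## outputs --------------------------------------------------------------
  if (!is.null(out_dir)) {
    emit(cell_meta, "cell_meta.tsv")
    emit(traj, "trajectory.tsv")
    emit(summ, "sample_summary.tsv")
    emit(data.frame(cell_id = names(levels), cnv_level = levels),
         "cnv_levels.tsv")
    cnv_tab <- data.frame(gene_id = cnv$genes$gene_id,
                          round(cnv$values, 4),
                          check.names = FALSE)
    emit(cnv_tab, "cnv_matrix.tsv")
    if (!is.null(res$crosstalk))
      emit(res$crosstalk$interactions, "crosstalk.tsv")
    if (!is.null(res$composition$subclone))
      emit(res$composition$subclone, "composition_subclone.tsv")
    log_line(log_con, "pipeline complete")
  }
  res
}

# Trajectory endpoint markers from the data itself: significantly up
# genes of the stem-like endpoint cells in the more stem-dominant
# subclone vs the differentiated endpoint cells of the other subclone.
derive_trajectory_markers <- function(E, cell_meta, undiff_type,
                                      diff_type, n_top = 50) {
  cm <- cell_meta[!is.na(cell_meta$subclone), , drop = FALSE]
  sub_of <- function(type) {
    tab <- table(cm$subclone[cm$cell_type == type])
    if (!length(tab)) stop("no '", type, "' cells with a subclone label")
    names(which.max(tab))
  }
  s_up <- sub_of(undiff_type); s_dn <- sub_of(diff_type)
  up_cells <- cm$cell_id[cm$cell_type == undiff_type & cm$subclone == s_up]
  dn_cells <- cm$cell_id[cm$cell_type == diff_type & cm$subclone == s_dn]
  if (length(up_cells) < 3 || length(dn_cells) < 3)
    stop("too few endpoint cells to derive trajectory markers")
  sub <- subset_expr(E, cells = c(up_cells, dn_cells))
  lab <- c(rep("undiff", length(up_cells)), rep("diff", length(dn_cells)))
  mk <- find_markers(sub, lab)
  pick <- function(group) {
    m <- mk[mk$group == group & mk$marker, , drop = FALSE]
    m <- m[order(m$p_value, -m$log_fold_change), , drop = FALSE]
    utils::head(m$gene_id, n_top)
  }
  list(undiff = pick("undiff"), diff = pick("diff"))
}

#' Run the bundled synthetic demo end-to-end
#'
#' Generates the default synthetic cohort, runs [run_pipeline()] on it
#' with parameters matched to the simulated library size, and returns the
#' pipeline results together with the generating truth.
#'
#' @param rng_seed global seed for both the cohort and the pipeline.
#' @param output_dir optional output directory.
#' @param sim a [sim_config()] overriding the default cohort.
#' @return list(results = pipeline outputs, cohort = the generated data).
#' @export
run_demo <- function(rng_seed = 0L, output_dir = NULL, sim = NULL) {
  cfgsim <- sim %||% sim_config(rng_seed = derive_seed(rng_seed, "cohort"))
  cohort <- generate_cohort(cfgsim)
  cfg <- pipeline_config(
    input = cohort,
    signatures = cohort$signatures,
    lr_pairs = demo_lr_pairs(),
    survival = cohort$truth$samples,
    undiff_markers = cohort$trajectory_markers$undiff,
    diff_markers = cohort$trajectory_markers$diff,
    min_genes = 250,
    output_dir = output_dir,
    rng_seed = rng_seed)
  list(results = run_pipeline(cfg), cohort = cohort)
}

#' Small synthetic ligand-receptor table for demos and tests
#'
#' Gene ids follow the synthetic cohort's naming; the MDK-NCL-style row
#' pairs the first two entries. Purely synthetic — users supply a real
#' L-R database for their own data.
#'
#' @param gene_ids optional pool to draw pair genes from.
#' @return data.frame (ligand, receptor, pathway).
#' @export
demo_lr_pairs <- function(gene_ids = sprintf("G%04d", seq_len(1200))) {
  idx <- round(seq(300, length(gene_ids), length.out = 12))
  data.frame(
    ligand = gene_ids[idx[1:6]],
    receptor = gene_ids[idx[7:12]],
    pathway = paste0("PW", 1:6),
    stringsAsFactors = FALSE)
}
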