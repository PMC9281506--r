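#' Configuration for the synthetic EPN-like cohort generator
#'
#' Describes a small ependymoma-like single-cell cohort: seven malignant
#' cell states along a neural-stem-cell (NSC) to ependymocyte (EpC)
#' differentiation gradient, non-malignant reference populations, two CNV
#' subclones carrying planted chromosome-segment gains/losses, multiple
#' samples split into primary and recurrent condition, and survival
#' outcomes whose hazard is tied to each sample's mean stemness.
#'
#' @param n_cells_per_type named integer vector, cells per cell type. Names
#'   must cover all `gradient_types`; any other names are taken as
#'   non-malignant types (copy factor 1 everywhere).
#' @param gradient_types ordered malignant states, most stem-like first.
#' @param n_chromosomes,genes_per_chromosome autosome layout; the gene
#'   universe is their product plus `mito_gene_count` MT- genes.
#' @param cnv_segments list of planted events, each a list with fields
#'   `subclone`, `chrom`, `start`, `end` (1-based gene indices within the
#'   chromosome, inclusive) and `factor` (multiplicative copy dosage, e.g.
#'   1.5 for a single-copy gain, 0.5 for a loss).
#' @param subclone_fractions named fractions of malignant cells per
#'   subclone; must sum to 1.
#' @param nb_dispersion negative-binomial size (shape) parameter shared by
#'   all genes; smaller means more overdispersion.
#' @param mito_gene_count number of MT- prefixed genes.
#' @param mito_fraction_mean target mean mitochondrial read fraction.
#' @param n_samples number of samples; cells of every type are spread
#'   across them.
#' @param condition_per_sample character vector (`"primary"`/`"recurrent"`)
#'   of length `n_samples`.
#' @param recurrent_stem_boost over-sampling factor for the three most
#'   stem-like malignant states in recurrent samples (plants the
#'   composition shift recurrent tumors show).
#' @param survival_effect hazard multiplier per unit of sample-mean planted
#'   stemness (stemness = 1 - pseudotime); larger means stem-rich samples
#'   die faster.
#' @param rng_seed integer seed; identical seeds give identical cohorts.
#' @param program_seed integer seed for the gene-level architecture
#'   (endpoint programs, silenced set, marker blocks). It defaults to a
#'   fixed value so cohorts generated with different `rng_seed` share the
#'   same biology and can serve as query/reference pairs; change it to
#'   sample a different gene universe.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_cells_per_type = c(
      "NSC-like" = 150, "NPC-like" = 150, "RGC-like" = 150,
      "GPC-like" = 150, "imEpC-like" = 150, "tEpC-like" = 150,
      "EpC-like" = 150,
      "OPC" = 350, "Microglia-like" = 100,
      "Endothelial-like" = 60, "Neuron-like" = 60),
    gradient_types = c("NSC-like", "NPC-like", "RGC-like", "GPC-like",
                       "imEpC-like", "tEpC-like", "EpC-like"),
    n_chromosomes = 8,
    genes_per_chromosome = 150,
    cnv_segments = list(
      list(subclone = "subclone1", chrom = "chr1", start = 1, end = 150,
           factor = 1.5),
      list(subclone = "subclone2", chrom = "chr2", start = 1, end = 150,
           factor = 0.5)),
    subclone_fractions = c(subclone1 = 0.5, subclone2 = 0.5),
    nb_dispersion = 5,
    mito_gene_count = 10,
    mito_fraction_mean = 0.05,
    n_samples = 8,
    condition_per_sample = rep(c("primary", "recurrent"), each = 4),
    recurrent_stem_boost = 3,
    survival_effect = 500,
    rng_seed = 1L,
    program_seed = 1987L) {

  cfg <- list(n_cells_per_type = n_cells_per_type,
              gradient_types = gradient_types,
              n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              n_genes = as.integer(n_chromosomes * genes_per_chromosome),
              cnv_segments = cnv_segments,
              subclone_fractions = subclone_fractions,
              nb_dispersion = nb_dispersion,
              mito_gene_count = as.integer(mito_gene_count),
              mito_fraction_mean = mito_fraction_mean,
              n_samples = as.integer(n_samples),
              condition_per_sample = condition_per_sample,
              recurrent_stem_boost = recurrent_stem_boost,
              survival_effect = survival_effect,
              rng_seed = as.integer(rng_seed),
              program_seed = as.integer(program_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$subclone_fractions) - 1) > 1e-9)
    stop("subclone fractions must sum to 1")
  if (!all(cfg$gradient_types %in% names(cfg$n_cells_per_type)))
    stop("every gradient type needs an entry in n_cells_per_type")
  if (any(cfg$n_cells_per_type < 0)) stop("negative cell counts")
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  for (seg in cfg$cnv_segments) {
    if (!all(c("subclone", "chrom", "start", "end", "factor") %in%
             names(seg)))
      stop("cnv segment missing a field")
    if (!seg$chrom %in% chroms)
      stop("cnv segment on unknown chromosome ", seg$chrom)
    if (seg$start < 1 || seg$end > cfg$genes_per_chromosome ||
        seg$start > seg$end)
      stop("cnv segment gene-index range outside its chromosome")
    if (seg$factor <= 0) stop("copy factor must be positive")
    if (!seg$subclone %in% names(cfg$subclone_fractions))
      stop("cnv segment refers to unknown subclone ", seg$subclone)
  }
  if (length(cfg$condition_per_sample) != cfg$n_samples)
    stop("condition_per_sample must have n_samples entries")
  if (!all(cfg$condition_per_sample %in% c("primary", "recurrent")))
    stop("conditions must be 'primary' or 'recurrent'")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$mito_fraction_mean < 0 || cfg$mito_fraction_mean >= 1)
    stop("mito_fraction_mean must lie in [0, 1)")
  invisible(cfg)
}

# Deterministic integer allocation of n units over weights (largest
# remainder), so the per-sample cell layout is reproducible without RNG.
allocate_counts <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic EPN-like single-cell cohort
#'
#' Draws UMI counts per gene and cell from a negative binomial whose mean
#' is `baseline type program x CNV copy factor x library-size factor`.
#' Malignant cells interpolate linearly between a broad stem-like program
#' and a sparser differentiated program according to their planted
#' pseudotime, so the number of detected genes per cell falls with
#' differentiation; each cell type additionally carries a dedicated block
#' of marker genes. CNV segments act multiplicatively on the means of
#' their genes in cells of the carrying subclone only (dosage model).
#' Sample survival times are exponential with hazard scaled by
#' `survival_effect^(sample-mean stemness)` and right-censored.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{counts}{[expr_matrix] of raw counts (genes x cells)}
#'     \item{genes}{gene annotation data.frame (gene_id, chrom, start, end)}
#'     \item{cell_meta}{data.frame (cell_id, sample_id, condition) plus
#'       empty cluster/cell_type/subclone/malignant columns the downstream
#'       stages fill}
#'     \item{truth}{list of `cells` (true_type, true_subclone,
#'       true_pseudotime, true_malignant) and `samples` (condition,
#'       survival_time, event, true_stemness) data.frames}
#'     \item{signatures}{named list of marker gene ids per cell type}
#'     \item{trajectory_markers}{list(undiff=, diff=) marker sets of the
#'       stem-like and differentiated endpoint states}
#'   }
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  ng <- config$n_genes
  gpc <- config$genes_per_chromosome
  chroms <- rep(paste0("chr", seq_len(config$n_chromosomes)), each = gpc)
  gene_ids <- sprintf("G%04d", seq_len(ng))
  types <- names(config$n_cells_per_type)
  grad <- config$gradient_types

  # The gene-level architecture draws from its own seed so cohorts with
  # different rng_seed share one biology (query/reference pairs).
  prog <- with_seed(config$program_seed %||% config$rng_seed, {
    ## --- endpoint mean programs -------------------------------------
    stem_prog <- stats::rlnorm(ng, meanlog = log(1.5), sdlog = 1)
    # The differentiated endpoint silences the weakest-expressed 35% of
    # each chromosome's genes: differentiation restricts expression
    # breadth (as it does in real tissue, where housekeeping-level genes
    # stay on) while the well-expressed, dosage-informative genes remain
    # active on every chromosome, so differentiation neither mimics nor
    # erases a chromosome-scale dosage shift.
    # Mass-balance the silencing: every chromosome loses the same
    # fraction of its expressed mass, so the shared silencing program of
    # differentiated cells cannot masquerade as a subclonal dosage shift.
    ord_all <- order(stem_prog)
    f_mass <- sum(stem_prog[ord_all[seq_len(round(0.35 * ng))]]) /
      sum(stem_prog)
    silenced <- integer(0)
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      o <- idx[order(stem_prog[idx])]
      cum <- cumsum(stem_prog[o]) / sum(stem_prog[idx])
      k <- which(cum >= f_mass)[1]
      silenced <- c(silenced, o[seq_len(k)])
    }
    silenced <- sort(silenced)
    diff_prog <- stem_prog
    diff_prog[silenced] <- 0.02
    # keep expected library sizes comparable between endpoints so the
    # detected-gene gradient reflects breadth, not depth
    diff_prog[-silenced] <- diff_prog[-silenced] *
      sum(stem_prog) / sum(diff_prog)

    ## --- marker genes ------------------------------------------------
    # Marker blocks are spread round-robin across all chromosomes so a
    # cell type's identity program never shifts one chromosome's average
    # (which the CNV inference would read as a dosage change).
    n_marker <- 12L
    n_blocks <- length(types) + 2L
    need <- n_marker * n_blocks
    if (ng < 2L * need)
      stop("gene universe too small for marker blocks")
    chrom_ids <- unique(chroms)
    pool <- lapply(chrom_ids, function(ch) sample(which(chroms == ch)))
    used <- integer(length(chrom_ids))
    seq_ch <- rep_len(seq_along(chrom_ids), need)
    picks <- integer(need)
    for (j in seq_len(need)) {
      ci <- seq_ch[j]
      used[ci] <- used[ci] + 1L
      picks[j] <- pool[[ci]][used[ci]]
    }
    marker_idx <- split(picks, rep(seq_len(n_blocks), each = n_marker))
    signatures <- stats::setNames(
      lapply(seq_along(types), function(i) gene_ids[marker_idx[[i]]]),
      types)
    nsc_traj <- marker_idx[[length(types) + 1L]]
    epc_traj <- marker_idx[[length(types) + 2L]]

    # marker blocks are quiet everywhere by default
    flat <- unlist(marker_idx)
    stem_prog[flat] <- 0.05
    diff_prog[flat] <- 0.05
    # gradient markers: monotone along pseudotime via the interpolation
    stem_prog[nsc_traj] <- 4; diff_prog[nsc_traj] <- 0.02
    stem_prog[epc_traj] <- 0.02; diff_prog[epc_traj] <- 4
    # non-malignant background: mid-breadth, no gradient-marker signal
    normal_prog <- (stem_prog + diff_prog) / 2
    normal_prog[c(nsc_traj, epc_traj)] <- 0.05
    list(stem_prog = stem_prog, diff_prog = diff_prog,
         normal_prog = normal_prog, marker_idx = marker_idx,
         signatures = signatures, nsc_traj = nsc_traj,
         epc_traj = epc_traj)
  })
  stem_prog <- prog$stem_prog; diff_prog <- prog$diff_prog
  normal_prog <- prog$normal_prog; marker_idx <- prog$marker_idx
  signatures <- prog$signatures
  nsc_traj <- prog$nsc_traj; epc_traj <- prog$epc_traj
  marker_boost <- 4

  with_seed(config$rng_seed, {
    ## --- cells: sample layout, pseudotime, subclones ------------------
    samples <- sprintf("S%02d", seq_len(config$n_samples))
    cond <- stats::setNames(config$condition_per_sample, samples)
    stem_types <- grad[seq_len(min(3L, length(grad)))]
    cell_type <- character(0); cell_sample <- character(0)
    for (t in types) {
      w <- ifelse(cond == "recurrent" & t %in% stem_types,
                  config$recurrent_stem_boost, 1)
      if (t %in% setdiff(grad, stem_types) && length(grad) > 3L)
        w <- ifelse(cond == "recurrent", 1 / config$recurrent_stem_boost, 1)
      nper <- allocate_counts(config$n_cells_per_type[[t]], w)
      cell_type <- c(cell_type, rep(t, sum(nper)))
      cell_sample <- c(cell_sample, rep(samples, nper))
    }
    nc <- length(cell_type)
    cell_ids <- sprintf("C%05d", seq_len(nc))
    is_mal <- cell_type %in% grad
    tau <- rep(NA_real_, nc)
    centers <- stats::setNames(
      seq(0, 1, length.out = length(grad)), grad)
    tau[is_mal] <- pmin(1, pmax(0, centers[cell_type[is_mal]] +
                                   stats::runif(sum(is_mal), -0.06, 0.06)))
    subclone <- rep(NA_character_, nc)
    subclone[is_mal] <- sample(names(config$subclone_fractions),
                               sum(is_mal), replace = TRUE,
                               prob = config$subclone_fractions)

    ## --- per-cell mean profiles --------------------------------------
    mu <- matrix(0, nrow = ng, ncol = nc)
    for (i in seq_len(nc)) {
      if (is_mal[i]) {
        m <- (1 - tau[i]) * stem_prog + tau[i] * diff_prog
      } else {
        m <- normal_prog
      }
      m[marker_idx[[match(cell_type[i], types)]]] <- marker_boost
      mu[, i] <- m
    }
    # planted CNV dosage, malignant carriers only
    for (seg in config$cnv_segments) {
      gidx <- which(chroms == seg$chrom)[seg$start:seg$end]
      carrier <- which(is_mal & subclone == seg$subclone)
      mu[gidx, carrier] <- mu[gidx, carrier] * seg$factor
    }

    ## --- mitochondrial genes -----------------------------------------
    nm <- config$mito_gene_count
    mito_total <- config$mito_fraction_mean /
      (1 - config$mito_fraction_mean) * colSums(mu)
    mu_mito <- matrix(rep(mito_total / nm, each = nm), nrow = nm)
    mu <- rbind(mu, mu_mito)
    gene_ids <- c(gene_ids, sprintf("MT-%d", seq_len(nm)))
    chroms <- c(chroms, rep("chrM", nm))

    ## --- draw counts ---------------------------------------------------
    libf <- stats::rlnorm(nc, 0, 0.1)
    mu <- sweep(mu, 2, libf, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = config$nb_dispersion),
                     nrow = nrow(mu))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
    rownames(counts) <- gene_ids; colnames(counts) <- cell_ids

    ## --- survival ------------------------------------------------------
    stemness <- vapply(samples, function(s) {
      mean(1 - tau[is_mal & cell_sample == s])
    }, 0)
    hazard <- 0.005 * config$survival_effect^stemness
    raw_time <- stats::rexp(config$n_samples, rate = hazard)
    censor <- 60
    surv <- data.frame(
      sample_id = samples, condition = unname(cond),
      survival_time = pmin(raw_time, censor),
      event = raw_time <= censor,
      true_stemness = unname(stemness),
      stringsAsFactors = FALSE)

    per_gene_pos <- stats::ave(seq_along(chroms), chroms, FUN = seq_along)
    genes <- data.frame(
      gene_id = gene_ids, chrom = chroms,
      start = (per_gene_pos - 1L) * 10000L,
      end = (per_gene_pos - 1L) * 10000L + 1000L,
      stringsAsFactors = FALSE)

    cell_meta <- data.frame(
      cell_id = cell_ids, sample_id = cell_sample,
      condition = unname(cond[cell_sample]),
      cluster = NA_integer_, cell_type = NA_character_,
      subclone = NA_character_, malignant = NA,
      stringsAsFactors = FALSE)

    truth_cells <- data.frame(
      cell_id = cell_ids, true_type = cell_type,
      true_subclone = subclone, true_pseudotime = tau,
      true_malignant = is_mal, sample_id = cell_sample,
      stringsAsFactors = FALSE)

    list(counts = expr_matrix(counts, gene_ids, cell_ids, "counts"),
         genes = genes, cell_meta = cell_meta,
         truth = list(cells = truth_cells, samples = surv),
         signatures = signatures,
         trajectory_markers = list(
           undiff = unique(c(gene_ids[nsc_traj], signatures[["NSC-like"]])),
           diff = unique(c(gene_ids[epc_traj], signatures[["EpC-like"]]))))
  })
}

#' Write a counts matrix in 10x-style MatrixMarket triplet layout
#'
#' Produces `matrix.mtx`, `genes.tsv` (gene_id, chrom, start, end) and
#' `barcodes.tsv` in `dir`, readable by [read_counts_mtx()]. Cell metadata,
#' if supplied, is written alongside as `cell_meta.tsv`.
#'
#' @param counts an `expr_matrix` with layer `"counts"`.
#' @param genes gene annotation data.frame matching the matrix rows.
#' @param cell_meta optional cell metadata data.frame.
#' @param dir output directory (created if absent).
#' @param gzip write `.gz` variants of all three files.
#' @return `dir`, invisibly.
#' @export
write_10x_mtx <- function(counts, genes = NULL, cell_meta = NULL, dir,
                          gzip = FALSE) {
  stopifnot(inherits(counts, "expr_matrix"), counts$layer == "counts")
  if (!is.null(genes) && nrow(genes) != length(counts$gene_ids))
    stop("gene table does not match matrix rows")
  if (!is.null(cell_meta) && nrow(cell_meta) != length(counts$cell_ids))
    stop("cell metadata does not match matrix columns")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(counts$values, "dMatrix"), "TsparseMatrix")
  ext <- if (gzip) ".gz" else ""
  open_fun <- if (gzip) gzfile else file
  mtx_path <- file.path(dir, paste0("matrix.mtx", ext))
  con <- open_fun(mtx_path, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    writeLines(paste(m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  close(con)
  gt <- if (is.null(genes)) {
    data.frame(gene_id = counts$gene_ids)
  } else genes
  con <- open_fun(file.path(dir, paste0("genes.tsv", ext)), "w")
  utils::write.table(gt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  con <- open_fun(file.path(dir, paste0("barcodes.tsv", ext)), "w")
  writeLines(counts$cell_ids, con)
  close(con)
  if (!is.null(cell_meta))
    utils::write.table(cell_meta, file.path(dir, "cell_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
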