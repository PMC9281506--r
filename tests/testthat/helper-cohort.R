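# Shared fixtures, built in code and memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default synthetic cohort with QC, normalization and aligned truth.
default_cohort <- function(seed = 1L) {
  memo(paste0("cohort", seed), {
    co <- generate_cohort(sim_config(rng_seed = seed))
    qc <- qc_filter(co$counts, min_genes = 250, max_mito_frac = 0.12,
                    min_cells_per_gene = 10)
    E <- normalize_E(qc$counts)
    truth <- co$truth$cells[match(E$cell_ids, co$truth$cells$cell_id), ]
    list(co = co, qc = qc, E = E, truth = truth)
  })
}

# CNV inference on the default cohort with the OPC reference.
default_cnv <- function(seed = 1L) {
  memo(paste0("cnv", seed), {
    cx <- default_cohort(seed)
    cm <- data.frame(cell_id = cx$truth$cell_id,
                     cell_type = cx$truth$true_type)
    ref <- sample_reference(cm, "OPC", 300, rng_seed = seed)
    cnv <- infer_cnv(cx$E, cx$co$genes, ref, counts = cx$qc$counts)
    list(cnv = cnv, ref = ref, levels = cnv_level(cnv, cx$qc$counts))
  })
}

# Louvain clusters of the default cohort.
default_clusters <- function(seed = 1L) {
  memo(paste0("clusters", seed),
       preprocess_cluster(default_cohort(seed)$E, rng_seed = 11L))
}

# Small two-program expression matrix with planted structure: group "hi"
# expresses the first `n_sig` genes strongly.
two_program_E <- function(n_genes = 120, n_cells = 80, n_sig = 15,
                          seed = 42) {
  set.seed(seed)
  hi <- rep(c(TRUE, FALSE), each = n_cells / 2)
  mu <- matrix(1, n_genes, n_cells)
  mu[seq_len(n_sig), hi] <- 6
  counts <- matrix(rpois(length(mu), mu * 3), n_genes, n_cells)
  em <- expr_matrix(counts, sprintf("g%03d", seq_len(n_genes)),
                    sprintf("c%03d", seq_len(n_cells)), "counts")
  list(E = normalize_E(em), hi = hi,
       sig = sprintf("g%03d", seq_len(n_sig)))
}

# independent brute-force Mann-Whitney permutation oracle (tie-aware U
# counted from pairwise comparisons, two-sided by distance from the mean)
mw_enum_oracle <- function(x, y) {
  vals <- c(x, y); n1 <- length(x); n <- length(vals)
  u_of <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  us <- utils::combn(n, n1, u_of)
  u_obs <- u_of(seq_len(n1))
  mean(abs(us - mean(us)) >= abs(u_obs - mean(us)) - 1e-9)
}

# independent Kruskal-Wallis enumeration oracle via group reassignment
kw_enum_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  ns <- table(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  ccor <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(gidx) {
    s <- sum(vapply(gidx, function(ix) sum(r[ix])^2 / length(ix), 0))
    (12 / (n * (n + 1)) * s - 3 * (n + 1)) / ccor
  }
  obs <- h_of(split(seq_len(n), groups))
  hs <- c()
  rec <- function(avail, sizes, acc) {
    if (length(sizes) == 1) {
      hs <<- c(hs, h_of(c(acc, list(avail)))); return(invisible())
    }
    cs <- utils::combn(length(avail), sizes[1])
    for (j in seq_len(ncol(cs))) {
      pick <- avail[cs[, j]]
      rec(setdiff(avail, pick), sizes[-1], c(acc, list(pick)))
    }
  }
  rec(seq_len(n), as.integer(ns), list())
  list(statistic = obs, p = mean(hs >= obs - 1e-9))
}

# two-group log-rank chi-square from first principles (hypergeometric
# variance), used as the independent check on the survival stack
logrank_chisq_oracle <- function(time, event, g1) {
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
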