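# clonetraj

Intratumoral heterogeneity analysis for single-cell RNA-seq of
ependymoma-like brain tumors: expression-inferred CNV subclones,
signature-based cell typing, a stemness/differentiation **trajectory
score**, composition and survival statistics, and ligand–receptor
crosstalk — as one reusable, fully testable R pipeline.

## The problem

Pediatric ependymoma (EPN) relapses frequently, and relapse tracks with
an undifferentiated, neural-stem-cell-like (NSC-like) tumor cell state.
Dissecting this from droplet scRNA-seq requires several bespoke
computations that are usually scattered across scripts:

* **Copy-number from expression.** Per-cell copy proxies are inferred by
  smoothing reference-centered log expression along the genome
  (101-gene moving average within chromosomes), denoising, and rescaling
  to a 0–2 copy scale with 1 = normal copy. The per-cell **CNV level**
  is the quadratic sum Σ s² of the re-standardized proxies
  (s = c − 1 ∈ [−1, 1]) over that cell's expressed genes; malignant
  cells and **subclones** are then called by a mixture split of the
  levels and Ward (ward.D2) clustering of the CNV profiles.
* **Module scores with binned controls.** The score of a gene set in a
  cell is mean(E over signature genes) − mean(E over expression-matched
  control genes), E = log2(1 + CPM/10). Cluster-level argmax over
  signature scores gives SE cell typing; the reverse direction (cluster
  markers scored on a typed reference) gives rSE and an agreement
  statistic.
* **Trajectory score.** score(cell) = module score of undifferentiated
  endpoint markers (NSC-like, stem-dominant subclone) − module score of
  differentiated endpoint markers (EpC-like, other subclone). Higher =
  more stem-like. Samples split into high/low at the mean of per-sample
  means feed Kaplan–Meier / log-rank survival comparison.
* **Composition and crosstalk statistics.** Two-sample Fisher–Pitman
  permutation tests (exact, asymptotic, Monte-Carlo) for cell-type
  composition; tie-aware Mann–Whitney / Kruskal–Wallis with exact
  small-sample enumeration; product-of-means ligand–receptor
  interaction scores with label-permutation p-values and a one-sided
  recurrent-vs-primary contrast.

A negative-binomial synthetic-cohort generator (`generate_cohort()`)
plants cell states along an NSC→EpC gradient, two CNV subclones,
primary/recurrent composition shifts and stemness-linked survival, so
every stage can be validated against ground truth without any download.

## Worked example

```r
library(clonetraj)

cohort <- generate_cohort(sim_config(rng_seed = 1))
cohort$counts
#> <expr_matrix> 1210 genes x 1620 cells, layer 'counts'

qc <- qc_filter(cohort$counts, min_genes = 250)   # synthetic-scale QC
E  <- normalize_E(qc$counts)

cm <- cohort$cell_meta
cm$cell_type <- cohort$truth$cells$true_type      # or se_classify()
ref <- sample_reference(cm, "OPC", 300, rng_seed = 1)
cnv <- infer_cnv(E, cohort$genes, ref, counts = qc$counts)
lev <- cnv_level(cnv, qc$counts)

mal <- classify_malignancy(lev, setNames(cm$cell_type, cm$cell_id), ref)
table(mal$malignant)
#> FALSE  TRUE
#>   570  1050        # exactly the 1,050 planted malignant cells

sub <- call_subclones(cnv, cells = names(mal$malignant)[mal$malignant])
sub
#> <subclone_result> k = 2 (mean silhouette 0.406)
#> subclone1 subclone2
#>       545       505

tr <- trajectory_score(E, cohort$trajectory_markers$undiff,
                       cohort$trajectory_markers$diff, rng_seed = 1)
sm <- summarize_by_sample(tr, cm)
sm[, c("sample_id", "mean_score", "group")]
#>   sample_id mean_score group
#> 1       S01 -0.7355012   low     # S01-S04: primary
#> 4       S04 -0.7519575   low
#> 5       S05  0.8473458  high     # S05-S08: recurrent
#> 8       S08  0.9795795  high

sv <- merge(cohort$truth$samples, sm[, c("sample_id", "group")])
names(sv)[names(sv) == "survival_time"] <- "time"
km_logrank(sv)$p_value
#> [1] 0.006727173   # high-trajectory samples die sooner
```

The two planted subclones (a 1.5× arm gain and a 0.5× arm loss) are
recovered at k = 2; the trajectory split separates recurrent from
primary samples perfectly on this cohort, and the planted
stemness–survival link reaches log-rank p ≈ 0.007 with only 8 samples.

`run_demo(rng_seed = 7, output_dir = "out")` runs the whole pipeline
(QC → clustering → SE typing → CNV → subclones → trajectory →
composition → survival → crosstalk) and writes TSV outputs plus a log.

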