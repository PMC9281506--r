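---
title: "Methods: CNV subclones, signature typing and trajectory scoring in clonetraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV subclones, signature typing and trajectory scoring in clonetraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetraj)
```

clonetraj re-implements, as a reusable and fully testable pipeline, the
computational core of a single-cell dissection of intratumoral
heterogeneity in ependymoma-like tumors: expression-inferred CNV subclone
calling, signature-enrichment cell typing, a stemness/differentiation
trajectory score, composition and survival statistics, and
ligand-receptor crosstalk comparison. This vignette documents the models,
their assumptions, the parameters that matter, and the choices made where
the design was genuinely open.

## Expression layers

All scoring operates on one of three layers of a gene-by-cell matrix:

* **counts** — raw UMI counts.
* **E** — `log2(1 + CPM/10)` where CPM is counts per million within each
  cell. UMI data carries no gene-length bias, so CPM is used where a
  read-based protocol would use TPM; the `/10` damps the inflation of
  lowly covered genes.
* **Er** — E centered per gene (mean 0 across cells), the relative
  expression layer.

Quality control keeps a cell when it has **at least 1,500 distinct
expressed genes** and **at most 12% mitochondrial reads** (genes with an
`MT-` prefix, case-insensitive — the community convention for human
data). Both thresholds are read strictly ("more than 12%" and "fewer
than 1,500" are removed), and the boundary cells are kept. Cell filters
run first; genes are then kept when expressed in at least 10 of the
*kept* cells. The order changes results and is part of the documented
contract; re-running QC on its own output reaches a fixed point after at
most two passes. For the bundled synthetic demo the gene floor is 250
rather than 1,500 — the simulated gene universe is only 1,210 genes, so
the human-scale default would empty the matrix; this is a property of
the simulated library, not of the method.

Clustering selects 5,000 highly variable genes by mean-binned normalized
dispersion (clamped to the gene universe), z-scales them, takes 50
principal components, and partitions a shared-nearest-neighbor graph
(k = 20, Jaccard weights) with Louvain at resolution 1 under a fixed
seed. Only determinism and separability are contractual; the algorithm
and resolution are configuration. Cell-cycle regression is out of scope.

## Expression-inferred CNV

CNV proxies are inferred from E by the standard expression-CNV recipe:
drop weakly expressed genes (mean E < 0.1 or expressed in < 5 cells),
order genes along the genome, center each gene on a copy-neutral
reference population, clip to ±3, smooth with a centered 101-gene moving
average within each chromosome (windows truncate at chromosome ends),
subtract each cell's median, and re-center on the reference. The
reference is a fixed-size sample (default 300) of one non-malignant cell
type, mirroring the use of OPCs as a common reference.

Two steps deserve comment because the underlying contract — "re-scaled
to 0–2, with 1 as the normal copy" — does not pin down a formula:

* **Denoising.** Residuals within 1.5 reference standard deviations of
  zero are soft-thresholded away before the copy mapping, the standard
  denoising step of expression-CNV practice. The default (1.5) was
  calibrated on the synthetic cohort so that a single-copy arm-level
  gain (1.5×) remains detectable in sparse, differentiated cells while
  copy-neutral cells sit at proxy ≈ 1. Setting `denoise_sd = 0` disables
  it.
* **0–2 mapping.** The remaining residual is scaled linearly so the
  reference cells' 1st–99th percentile band spans one copy
  (log2 0.5 .. log2 1.5), passed through `2^x`, and clamped to [0, 2].
  The *contract* is the calibration invariant — the mean proxy of
  reference cells lies in [0.95, 1.05] — not the mapping's internals.

The per-cell **CNV level** is the quadratic sum of the re-standardized
proxies (`s = c − 1`, so s ∈ [−1, 1]) over the genes that cell expresses
(raw count > 0; the definition is ambiguous in prose and this reading is
fixed here). A copy-neutral cell scores exactly 0.

**Subclones** are called by Ward (ward.D2) hierarchical clustering of
Euclidean distances between cell CNV profiles, with k chosen by maximal
mean silhouette over 2..6 unless fixed; a best silhouette below 0.1
flags the result low-confidence. **Malignancy** is a documented
operationalization of a narrative procedure: a cell's level must exceed
2.5 times the median level of the copy-neutral reference — well over
twice the copy-neutral background burden — and the per-cell calls are
smoothed by majority vote within each (transcriptomic) cluster;
reference cells are never called malignant. Without a reference the
level distribution is split with a 2-component Gaussian mixture on the
log scale (Otsu threshold as fallback; the log scale because levels are
non-negative and right-skewed), and effectively unimodal levels flag
the threshold unreliable. Two alternatives were evaluated and rejected:
requiring a cluster's mean to exceed the global median level discards
the weakest-signal (most differentiated) tumor cells whenever malignant
cells are the majority, and upper-tail reference quantiles are unstable
because the reference's own rare noise excursions populate the gap
between normal and weakly aberrant cells.

**Differential CNV** between two cell groups is a per-gene two-sided
Mann–Whitney test on the proxies with Benjamini–Hochberg adjustment;
the effect is the difference of group mean proxies.

## Signature scoring and cell typing

The **module score** of a gene set is the mean E over the signature
genes minus the mean E over expression-matched control genes: genes are
binned into 25 equal-frequency bins of their average expression, and
each signature gene draws 100 controls from its bin (with replacement
when a bin is smaller than the request, so small synthetic gene
universes cannot crash the scorer). Bin and control counts follow the
method this scoring style originates from; they are configurable because
no value is contractual. A random gene set scores near zero by
construction, which the tests verify (|mean| < 0.05 over 50 seeded
draws).

**SE** (signature enrichment) classification scores every signature on
every cell, averages within clusters, and assigns each cluster the
argmax cell type; ties break by input order with a warning. **rSE**
reverses the direction: markers of each query cluster (one-vs-rest
tie-aware Mann–Whitney with BH, positive fold change, top 50 by p) are
scored on a typed reference, and the cluster takes the reference type
with the highest mean score. The SE/rSE agreement statistic — the
proportion of concordant calls plus the Pearson correlation of the two
cluster-by-type score tables — is this package's definition; the source
procedure reports only a qualitative correlation.

Marker fold changes are differences of mean E, i.e. log2-scale ratios,
so the 0.25 threshold reads as ~19% expression difference.

The **undifferentiation score** is a deliberately simple gene-count
based differentiation proxy (full differentiation-potential frameworks
are out of scope): per-cell expressed-gene counts g, per-gene Pearson
correlation with g, mean E over the 200 most correlated genes,
optional k-NN smoothing, then rank-normalization to [0, 1] (1 = least
differentiated). If g is constant the score degrades to a flagged
constant.

## Trajectory score and survival

The **trajectory score** of a cell is the module score of the stem-like
endpoint markers (NSC-like cells of the stem-dominant subclone) minus
the module score of the differentiated endpoint markers (EpC-like cells
of the other subclone). Both components are computed on the same layer
with the same binning and the same control seed so their difference is
meaningful; the score is exactly antisymmetric under swapping the marker
sets, and identical sets give exactly zero. Samples are stratified at
the unweighted mean of per-sample mean scores ("high" strictly above,
ties low); the unweighted mean of sample means — not the pooled-cell
mean — is used because samples are the units of the survival analysis.

Survival uses Kaplan–Meier product-limit curves with right censoring and
the two-group log-rank test (hypergeometric variance, chi-square(1)
p-value), via the survival package; the tests verify the statistic
against a from-first-principles implementation and the p-value against a
100,000-draw permutation null. Group comparisons of scores use the
package's tie-aware Mann–Whitney and Kruskal–Wallis tests, which switch
to exhaustive enumeration for small samples (base R's implementations
approximate in the presence of ties).

## Composition statistics

The two-sample **Fisher–Pitman permutation test** uses the linear
statistic T = sum of responses in one group. The exact mode enumerates
all assignments and counts those with |T − E[T]| at least the observed
distance (two-sided); the asymptotic mode standardizes T by its exact
permutation mean and variance and doubles the normal tail; Monte-Carlo
sampling uses the +1 correction so p is never 0. How cell-type
composition enters a two-sample test is not recoverable from the source
prose; the implemented operationalization tests each cell type
separately — indicator responses per cell for within-sample subclone
contrasts, per-sample type proportions for condition contrasts — with
BH across types, and exposes the generic test separately.

A note on exact-vs-asymptotic agreement: the exact two-sided p is
discrete with atom mass 2/choose(n, n1) — about 0.03 at 4 vs 4 — and
with heavy-tailed responses the small-sample permutation distribution
can be multimodal, so no continuous approximation tracks every dataset
to 0.02. The tests therefore bound the *mean* absolute deviation
between the asymptotic and exact p across 100 random small datasets
(observed ≈ 0.018); skewness-corrected (Edgeworth) and t-mapped
variants were evaluated and do not materially improve on the plain
normal approximation, which is what the field's permutation-test
tooling uses.

## Ligand-receptor crosstalk

The interaction score of (source, target, ligand, receptor) is mean E of
the ligand in the source type times mean E of the receptor in the target
type — a product-of-means statistic in the CellPhoneDB tradition,
deliberately simpler than pathway-level communication-probability
models, which are out of scope. Significance comes from shuffling
cell-type labels (p = (1 + #null ≥ observed)/(n_perm + 1), BH across
tuples); pairs with missing genes are retained with score 0 and p 1,
flagged. The recurrent-vs-primary contrast tests each ligand/receptor
gene in each cell type with a one-sided Mann–Whitney (recurrent >
primary), matching the directional claim it operationalizes.

## The synthetic cohort

Every stage is exercised on a built-in generator whose defaults are the
study conditions of the test suite:

* 7 malignant states (NSC-like → EpC-like) × 150 cells along a
  pseudotime gradient, plus OPC (350), microglia-like (100),
  endothelial-like (60) and neuron-like (60) non-malignant cells;
* 8 chromosomes × 150 genes plus 10 `MT-` genes; counts are negative
  binomial (shared size 5, lognormal library factors, ≈3,000 UMI/cell —
  a typical droplet-protocol regime);
* two equally sized subclones with arm-level events: a 1.5× gain of
  chr1 in subclone 1 and a 0.5× loss of chr2 in subclone 2, acting
  multiplicatively on expression means in carrier cells only (the
  dosage model that underlies expression-inferred CNV);
* malignant mean profiles interpolate linearly between a broad
  stem-like program and a differentiated program that silences the
  weakest-expressed 35% of each chromosome's genes, so expressed-gene
  counts fall along the gradient. Silencing is stratified within
  chromosomes and mass-balanced across them, and each cell type's
  12-gene marker block is spread round-robin over all chromosomes: both
  choices exist so that differentiation and cell identity change
  expression *breadth* and *programs* without mimicking (or erasing) a
  chromosome-scale dosage shift. Real tumors do harbor such confounders;
  the generator deliberately separates the axes so each stage's recovery
  can be attributed;
* mitochondrial means are set so the realized mito fraction averages
  5%;
* 8 samples (4 primary, 4 recurrent); recurrent samples over-sample the
  three most stem-like states 3:1 (and under-sample the differentiated
  ones), planting the composition shift recurrent tumors show; sample
  survival is exponential with hazard 0.005 ×
  500^(sample-mean stemness), censored at 60 — about a 3.5-fold hazard
  ratio between condition groups, so the hazard ordering is recoverable
  from 8 samples. The effect sizes are chosen for testability (the
  source does not state its subclonal effect sizes); they are not
  calibrated to any real cohort.

What passing tests do **not** show about real data: the generator has no
doublets, ambient RNA, batch effects, cell-cycle structure, or
expression-CNV confounding between differentiation state and dosage —
precisely the artifacts that make real expression-inferred CNV hard. The
recovery rates on synthetic data are upper bounds, not forecasts.

## Numerical choices and degenerate inputs

* Stage seeds derive from one global seed by a fixed hash, so stages are
  reproducible yet decoupled; all results are bit-identical under a
  fixed seed.
* Exhaustive enumeration in the rank tests caps at 20,000 assignments;
  beyond that the tie-corrected normal / chi-square approximations take
  over (they agree with the exact path to |Δp| < 0.02 at n ≤ 10 per
  group, which the tests enforce).
* Constant responses give p = 1 by convention throughout; empty groups,
  empty signatures, zero-total cells and all-censored survival inputs
  raise explicit errors or flagged fallbacks rather than propagating
  NaN.
* Ties: argmax cell-type assignment breaks by input order (warned);
  sample stratification sends exact ties to "low"; the subclone count
  falls back to a flagged single cluster when profiles are identical.

## Problem sizes

The test suite and the acceptance script run the default cohort
(≈1,620 cells × 1,210 genes, ≈1,050 malignant), 100-dataset
small-sample oracle sweeps, 400-permutation crosstalk nulls and a
100,000-draw log-rank permutation null; these sizes keep the full suite
in the minutes range on a single core while leaving the planted effects
comfortably recoverable.
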