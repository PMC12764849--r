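---
title: "Tracking tumor pathway archetypes across treatment cycles"
author: "scArchetypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking tumor pathway archetypes across treatment cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Serial biopsies taken during repeated intraperitoneal chemotherapy cycles
make it possible to watch a tumor adapt: pathway activity drifts from cycle
to cycle, and the mixture of functionally distinct cancer-cell
subpopulations ("archetypes") shifts under treatment pressure.
**scArchetypes** implements the analysis chain for such longitudinal
single-nuclei RNA-seq cohorts:

1. QC filtering and library-size log-normalization;
2. per-cell single-sample gene-set enrichment (ssGSEA) scoring;
3. per-feature linear modeling of pathway scores or gene expression against
   the treatment-cycle index, with Benjamini–Hochberg FDR control;
4. SVD reduction of pathway-score space, removal of the batch-carrying
   component, consensus-clustering selection of the number of archetypes by
   the proportion of ambiguous clustering (PAC), SNN–Louvain clustering,
   Wilcoxon archetype profiles, and per-cycle archetype proportions;
5. an AUC-gated rank-correlation classifier that rescues cells whose
   copy-number-based malignancy call was ambiguous.

A negative-binomial cohort simulator with planted ground truth backs every
stage, so each statistical claim the package makes is testable.

```{r quickstart, eval = FALSE}
library(scArchetypes)

bundle <- simulateCohort(SimParam(seed = 1))
sce <- logNormalize(qcFilter(bundle$sce))
scores <- ssgseaScores(sce, bundle$geneSets)

fits <- fitTemporalLinear(scores)              # per-patient cycle slopes
emb <- removeBatchComponent(reduceSVD(scores),
                            colData(sce)$patient)
cons <- consensusSelectK(emb, ConsensusParam(seed = 1))
arch <- clusterToK(emb, selectedK(cons), seed = 1)
archetypeProportions(archetypeLabels(arch), colData(sce))
```

Or in one call, `runPipeline(list(simulate = list(), seed = 1,
outdir = "run1"))`, which also writes a content-hashed manifest.

# The ssGSEA statistic

For one cell, genes are ranked by decreasing expression; the rank statistic
assigns $r = N$ to the top gene and $r = 1$ to the bottom, with ties
(including the zero block of sparse data) averaged. Walking the ordered
list, the in-set weighted empirical CDF

$$P^G_W(i) = \frac{\sum_{j \in S,\ \mathrm{pos}(j) \le i} r_j^\alpha}
                  {\sum_{j \in S} r_j^\alpha}$$

is compared with the out-of-set ECDF
$P_{NG}(i) = |\{j \notin S : \mathrm{pos}(j) \le i\}| / (N - |S|)$, and the
enrichment score is the full running sum
$ES = \sum_{i=1}^{N} \left[ P^G_W(i) - P_{NG}(i) \right]$ — not the maximum
deviation used by the two-sample GSEA statistic. With
`normalize = TRUE` (the default) all scores are divided by the global
max − min of the matrix, an order-preserving rescale to unit range.

Choices that matter:

* **α = 0.25** is the conventional rank-weight exponent; it is exposed in
  `SsgseaParam()` and snapshotted into the output metadata for audit.
* **Ties are averaged** and tied genes are walked in lexicographic gene-name
  order, which makes scores deterministic on sparse data and invariant to
  permutations of the input rows.
* Because the statistic depends only on within-cell ranks, it is invariant
  to any strictly monotone per-cell transform. This is why plain log-CPM is
  used as the pre-scoring transform: fancier normalizations that act
  monotonically per cell produce identical scores, so the archetype
  pipeline is insensitive to that choice. The transform is recorded in
  `metadata(.)$normalization`.
* Sets that vanish after intersection with the measured genes, cover all
  genes (the out-of-set ECDF is then undefined), or fall outside
  `[minSize, maxSize]` are dropped with warnings.

# Quality control

Cells are kept when `minFeatures < n_features < maxFeatures` and
`pct_mt < maxPctMt` — all strict inequalities, with defaults 300, 8000 and
5%. The assumed doublet rate (default 4%) is carried as provenance
metadata only; doublet detection itself is upstream of this package.
Filtering is idempotent and an empty result is a warning, not an error, so
pipelines can surface the condition gracefully.

# Temporal linear models

Every feature (a pathway score, or a gene's log-normalized expression) is
regressed on the numeric cycle index with ordinary least squares, cells as
observations, one fit per patient; biopsy sites within a cycle are pooled.
The slope ("estimate"), its standard error, the two-sided $t$-test p-value
and the BH-adjusted FDR are reported per (patient, feature), and BH is
applied within each patient and feature family. Fitting uses
`limma::lmFit` with classical (unmoderated) $t$ statistics, which is exactly
per-feature OLS computed in one pass.

Modeling cells as independent observations mirrors the single-term design
the analysis is built around; it ignores within-biopsy correlation, so
p-values on real data are anti-conservative in absolute terms and are best
read as a ranking. This is a known limitation, not an accident.

Degenerate inputs are handled explicitly: a patient observed at a single
cycle is skipped with a warning; a constant feature reports estimate 0 with
missing p and FDR; a feature fit exactly (zero residual) reports p = 0.

`volcanoTable()` classes features as `up`/`down`/`ns` with *strict*
cutoffs — a feature at exactly FDR = 0.05 is not significant.

# Archetype discovery

**Reduction.** The cells × pathways score matrix is column-centered (not
variance-scaled) and decomposed by SVD; the smallest leading set of
components reaching 90% cumulative variance is retained. Scaling to unit
variance happens only afterwards, inside the batch-distance computation —
the two steps are deliberately ordered this way.

**Batch component.** With more than one patient, components are scaled to
unit variance, the absolute difference of batch-group means is computed per
component (maximum pairwise difference if there are more than two groups),
and exactly one component — the argmax — is removed. Ties resolve to the
lowest index. If the largest separation is below 0.1 SD a warning is
emitted; removal still happens unless `removeNegligible = FALSE`.
Per-patient runs skip this step entirely. A global per-patient offset on
the gene log-means concentrates, by design of the simulator, in a single
SVD direction; note that when strong cluster structure coexists with the
batch, the score-space image of a gene-space shift is not exactly
orthogonal to the cluster contrast, so single-component removal captures
the identifiable (orthogonal) part. For this reason the package's
direction-recovery experiments use cluster-free cohorts, while the
"between-patient distance strictly decreases" property is checked in all
settings.

**K selection.** For each candidate k (default 2–10), 100 rounds of
k-means run on fresh 80% subsamples, one random start per round — the
round-to-round stochasticity is precisely what the stability estimate
measures. A cell pair's consensus is its co-clustering count divided by its
co-sampling count; pairs never drawn together are excluded rather than
imputed (at 100 × 80% a pair is co-drawn ~64 times in expectation, so
exclusion is rare). PAC is the fraction of off-diagonal consensus values
strictly inside the open band (0.1, 0.9); stability is 1 − PAC; the
selected k maximizes stability with ties broken toward the smallest k.
Subsamples are drawn from an iteration-indexed seed stream, so every k sees
the same draws.

**Clustering.** Cells are clustered by Louvain modularity on a shared
nearest-neighbor graph (20 Euclidean neighbors including self, Jaccard
weights, edges below 1/15 pruned). The Louvain resolution is found by
monotone bisection on [0.01, 5] until the cluster count matches the
consensus-selected k (at most 30 steps); an unreachable target returns the
nearest achievable count with a warning and the realized resolution. This
bisection is the explicit bridge between the stability-selected k and
modularity clustering, which has no direct k parameter.

**Characterization and tracking.** Each archetype's profile is the top 20
pathways by FDR (then effect size) among those with positive mean-score
difference versus all other cells, using two-sided Wilcoxon rank-sum tests
BH-adjusted within archetype. Proportions per (patient, cycle) sum to one;
groups without clustered cells are omitted with a warning. A small
companion, `kmeansCnaSubclones()`, clusters per-cell copy-number profiles
with seeded k-means (K = 2 by default, 10 restarts) for subclone tracking.

# Malignancy rescue

Copy-number inference tools confidently label most cells `diploid` or
`aneuploid` but leave a `not.defined` remainder. The rescue classifier is
the core mechanism of reference-based annotation: per-label mean
log-normalized profiles over a variable-gene panel (count
dispersion = variance/mean, top 2000 by default), Spearman correlation of
each cell with each profile, and assignment by argmax correlation. The
iterative fine-tuning used by full reference annotators is intentionally
omitted — with two labels it adds nothing specifiable.

Performance is estimated by stratified cross-validation (5 folds, reduced
with a warning when the rarest label is small): held-out cells are scored
by the correlation *margin* (a label's correlation minus the best
competitor's), one-vs-rest AUC is computed per label on the pooled held-out
cells, and their unweighted mean is `cvAuc`. The gate is strict:
predictions are applied only when `cvAuc > 0.7`. A rejected model leaves
every label untouched. Rescued cells are flagged in a `ploidy_source`
column; confidently labeled cells are never altered. The variable-gene
panel is selected once on all confidently labeled cells rather than
re-selected per fold; with the panel sizes involved this has negligible
optimism and keeps the reference profiles comparable across folds.

# The cohort simulator

`simulateCohort()` draws negative-binomial counts with

$$\log \mu_{gc} = \text{baseline}_g + \text{program}_{g,a(c)} +
  \text{cycle}_c \cdot \text{slope}_g + \text{batch}_{g,p(c)}
  \; (+ \log \text{dosage}_g \text{ for aneuploid cells}),$$

library-size factors lognormal (SD 0.3 on the log scale), and per-gene
baselines scaled to a target mean library size. Each cell draws its
archetype from a per-(patient, cycle) mixing schedule; true ploidy is
aneuploid with a configurable fraction; a fraction of cells have their
observed ploidy masked to `not.defined`. Copy-number dosage acts
multiplicatively on contiguous gene-index blocks — a stand-in for genomic
position. The same seed yields bit-identical output.

The default parameters describe a two-patient serial-biopsy study: one
patient sampled over six cycles whose metabolism-like archetype rises from
an even split to ~70% of cells at cycle 4 before collapsing to ~34% at
cycle 6, and one patient sampled over two cycles with a stable ~69/64%
dominant archetype; archetype programs put a 1.0 log-fold effect on 60
genes; the batch offset SD is 0.5; NB size is 10; trend programs drift at
±0.01–0.02 per cycle, the magnitude scale of reported pathway drifts in
longitudinal tumor studies.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: transcriptome-wide gene–gene correlation beyond
the planted programs, ambient RNA, doublets, cell-cycle structure, or
platform-specific count artifacts. Recovery results on this generator
demonstrate correctness of the machinery under its stated model, not
robustness to every failure mode of real single-nuclei data.

# Numerical and design notes

* **Slope recovery is assessed at the gene level.** The planted per-cycle
  drift acts on gene log-means, which is the OLS estimand for
  log-normalized expression of adequately expressed genes (the log1p
  attenuation factor is CPM/(1+CPM), so recovery experiments filter to
  ≥ 30 CPM, where the residual bias is an order of magnitude below the
  slope standard error). Pathway-score slopes are monotone reflections of
  the drift without a closed-form correspondence, so confidence-interval
  coverage of the planted value is only well-defined for genes. Trend
  programs cover ~1% of the transcriptome by default, keeping the
  compositional distortion of CPM normalization negligible.
* **Determinism.** All randomness flows from explicit seeds through named
  per-stage substreams; repeated runs with the same configuration produce
  identical selected k, labels, proportions, and file hashes.
* **Degenerate subsamples.** If a consensus subsample has no more distinct
  embedding rows than k, cells are clustered by row identity, so repeated
  points always co-cluster and the point-mass contract (PAC = 0) holds.
* **Problem sizes.** The recovery experiments shipped with the package use
  500 cells per cycle for temporal and proportion recovery, 600-cell
  cohorts for K-selection and batch-removal (20 seeds each), and
  ~1100-cell cohorts for the classifier gate — sizes at which the binomial
  and OLS error budgets make the stated tolerances meaningful.
* **Proportion tolerances.** At 500 cells per cycle the binomial SD of a
  realized archetype fraction is ~2.2 percentage points, so realized
  fractions are compared to the planted schedule within 3 binomial SDs,
  while the clustering-recovery error (recovered vs realized) is held to
  5 percentage points.

# Limitations

Cells are treated as independent in the temporal models (no patient- or
biopsy-level random effects); consensus k-means assumes roughly convex
archetypes in the reduced space; the rescue classifier presumes the
undefined cells are drawn from the same two populations as the confident
ones; and the simulator's independence assumptions are listed above. The
archetype analysis is clustering in pathway-score space — it is not
archetypal analysis in the convex-hull sense, and no trajectory or spatial
inference is attempted.
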