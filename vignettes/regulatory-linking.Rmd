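---
title: "Models and methods in creglink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in creglink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

creglink analyzes paired single-cell chromatin accessibility (scATAC-seq)
and expression (scRNA-seq) data from multi-sample tumor cohorts. Its goal is
to connect distal regulatory elements to the genes they control, to
characterize which elements and transcription factors (TFs) act specifically
in tumor cells, and to extract recurrent intratumor expression programs.
This vignette explains the statistical models behind each stage, the
parameters that matter, the design choices we made where several reasonable
options existed, and what the synthetic validation cohort does and does not
establish.

## Quality control

Per-cell ATAC quality is summarized by total fragment counts in peaks, the
nucleosome signal and TSS enrichment. The literature names these metrics but
rarely fixes formulas, so we state ours:

* **TSS enrichment** — Tn5 insertions (both fragment ends) are aggregated
  over windows of ±1000 bp around every transcription start site. The score
  is the mean insertion count per base over the window divided by the mean
  count per base in the outer 100 bp flanks (positions 901–1000 bp from the
  TSS on both sides). A pseudocount of 0.5 is added to the flank insertion
  total, so cells without flank insertions receive a large but finite score;
  cells with no insertions near any TSS score 0.
* **Nucleosome signal** — the ratio of mononucleosome-length fragments
  (147–294 bp) to subnucleosomal fragments (< 147 bp). A cell with no
  subnucleosomal fragments receives `Inf` (and fails any upper bound).

Filtering bounds are strict inequalities exactly as printed in the QC
tables returned by `qc_thresholds()`: ATAC cells need counts in
(2000, 30000), nucleosome signal < 4 and TSS enrichment > 2; RNA cells need
counts in (500, 50000), detected features in (500, 6000) and mitochondrial
percentage < 25; multiome cells use (1000, 20000) ATAC and (500, 25000)
RNA count bounds. A cell sitting exactly on a bound is removed. These
defaults describe deeply sequenced full-scale datasets; the synthetic
pipeline configuration uses proportionally scaled bounds because a
desk-scale cohort with ~2400 peaks cannot produce thousands of counts per
cell.

## Metacells

Sparse single-cell accessibility is densified by aggregating k-nearest
neighbor groups of `k = 50` cells in an LSI embedding (term frequency ×
`log(1 + n_cells / peak_df)`, truncated SVD; the first component is dropped
when it correlates with depth above 0.9). Seed cells are drawn without
replacement; a group is discarded when its Jaccard overlap with an accepted
group exceeds 0.8. The groups computed on the ATAC embedding are applied to
both modalities of the paired cells; for unpaired data the package refuses
rather than guessing a cross-modal alignment. The number of seed cells
(default 200) and the overlap cap are configurable.

## Co-accessibility

Peak–peak co-accessibility is estimated with a graphical lasso on the
empirical correlation matrix of log-normalized metacell accessibility,
computed per overlapping genomic window (width 500 kb, stepped by half a
window) with a maximum interaction distance of 500 kb. The penalty grows
linearly with distance, `rho_ij = distance_penalty_scale * d_ij / window`,
with a small ridge on the diagonal; the reported score is the scaled
negative precision entry `-omega_ij / sqrt(omega_ii * omega_jj)`, averaged
over the windows containing a pair. The reference implementation of this
idea calibrates its penalty by genome subsampling; we use a fixed,
configurable `distance_penalty_scale` (default 1) instead, which keeps the
estimator deterministic and testable against the closed-form two-variable
solution. One practical consequence of the linear penalty is that pairs
beyond roughly 150 kb are strongly shrunk: distal regulation near the 500 kb
cap will rarely clear a fixed score cutoff.

A fixed half-window tiling cannot guarantee that every pair within 500 kb
shares a window while also never co-windowing more distant pairs; our tiling
guarantees coverage for pairs within 250 kb (one step) and never emits pairs
beyond 500 kb. Since both planted and most biological enhancer–promoter
pairs fall well inside one step this is immaterial in practice, but it is a
property worth knowing when interpreting sparse long-range scores.

## Peak–gene links and the trans-chromosomal null

For every gene, candidate peaks are those with centers within ±500 kb of the
strand-aware TSS on the same chromosome. The Pearson correlation `r` between
log-normalized aggregated accessibility and expression is computed across
metacell groups. Raw correlations are biased by shared cell-type structure,
sequencing depth and library composition, so each gene is calibrated against
its own trans-chromosomal null: for each chromosome, 1000 peaks from other
chromosomes are drawn once (shared by all genes of that chromosome) and
correlated with the gene; the null mean and standard deviation convert `r`
into `z = (r - mu0) / sd0` and a two-sided normal p-value. Two-sided testing
is our choice — the sidedness is genuinely open and repressive distal
elements are plausible — and is configurable. Benjamini–Hochberg adjustment
is pooled across all candidate pairs of a cancer type.

A link is **reliable** when its FDR is below 0.1 (0.2 for ovarian cancer,
where the published analysis relaxed the cutoff) *and* the peak's best
co-accessibility to a promoter peak of the gene (TSS ± 1 kb, a configurable
definition the source analyses leave unstated) exceeds 0.2. A peak that is
itself the gene's only promoter peak has no partner to be co-accessible
with and is never called reliable; promoter-proximal regulation is the
domain of the promoter peak itself rather than of a distal link.

## Differential accessibility and conserved regions

Cell-type marker peaks are found by one-vs-rest Wilcoxon rank-sum tests on
log-normalized accessibility with detection-fraction (`min_pct = 0.05`) and
fold-change (`log2 FC >= 0.25` on expm1-means with pseudocount 1) pre-gates
and a BH post-gate at 0.05 — the standard marker-test recipe, re-implemented
because no single-cell framework is a dependency here. Comparisons with at
most 16 cells use an exact, tie-aware rank-sum distribution computed by
dynamic programming; larger ones use the tie-corrected normal approximation
with continuity correction.

A DAR is cancer-exclusive when no same-cell-type DAR from another cancer
overlaps it by 1 bp or more. Conserved regulatory regions intersect each
cancer's reliable-link peaks with its cell-type DARs, merge the union across
cancers by iterative overlap (greedy selection of the highest-scoring
region, score `-log10 FDR`, ties by fold change then coordinates), and keep
merged regions supported by at least two cancer types. We merge before
applying the two-cancer filter; the opposite order would discard
single-cancer regions before they can contribute support to an overlapping
region from another cancer, which we consider less faithful to the intent
of a conserved set.

## Motif deviations, footprints and tumor-specific TFs

Motif scanning converts position frequency matrices (JASPAR text format) to
log-odds against a uniform background (total pseudocount 0.8); a peak
matches when any position on either strand reaches 80% of the maximum
achievable score, with `N` scoring the background expectation.

Deviation scores follow the bias-corrected recipe: the observed count in
motif-matched peaks per cell is compared with `E = cell_total * sum(matched
peak count fractions)`; the raw deviation `(obs - E) / E` is standardized by
the mean and standard deviation of the same quantity over 50 background peak
sets matched on GC content and mean accessibility (equal-occupancy bins on a
2-D grid with a ~50-bin budget). A motif matching every peak has raw
deviation exactly zero, and in the absence of differential motif activity
the z-scores are approximately standard normal per motif — both properties
are exercised in the test suite.

Footprint profiles aggregate Tn5 insertions over ±250 bp around motif
sites in a cell-type pseudo-bulk, normalized by the mean insertion count in
the 200–250 bp flanks. We omit hexamer-based Tn5 sequence-bias correction:
the synthetic generator has no sequence bias, and the normalization hook
accepts a bias table should real data require one.

A TF is called **tumor-specific** when three criteria hold simultaneously
against normal epithelial cells: higher deviation z (Wilcoxon BH FDR
< 0.05), a higher flank-normalized footprint maximum in the tumor
pseudo-bulk (our operationalization of "increased binding" — no standard
scalar exists), and elevated TF-gene expression (log2 FC > 0.25, Wilcoxon
BH FDR < 0.05). The published analyses describe these criteria
qualitatively; the FDR and fold-change gates are our declared defaults.

## Intratumor programs and meta-programs

For every sample with more than 500 tumor cells, log-normalized expression
of the tumor cells is centered per gene and clipped at zero, and consensus
NMF (KL-divergence multiplicative updates, the Brunet variant) is run for
ranks 2–6 with 30 restarts (10 in the reduced-scale validation runs). A run
stops once the argmax-H cluster assignment has been stable for four
consecutive 10-iteration checks — the connectivity stopping rule of the
original consensus-NMF recipe — or after 300 iterations. The consensus
matrix records co-clustering fractions across restarts; robustness is the
Pearson correlation between consensus distances and the cophenetic
distances of their average-linkage dendrogram.

The rank is chosen immediately before the largest drop of the cophenetic
coefficient. Because the coefficients are estimated from finitely many
restarts, we treat drops within half of the maximum drop as ties and return
the smallest such rank; this parsimony-leaning tie rule is our extension of
the basic "smallest k on ties" convention and is controlled by
`select_k(drop_tol =)`. On cleanly separable data the cophenetic curve
declines only gently beyond the true rank (extra factors consistently
absorb the same residual structure), and the strict single-largest-drop
reading flips between adjacent ranks on restart noise; the tolerant rule is
stable while reproducing every textbook case, including curves with one
sharp cliff.

Programs are summarized by their top 100 genes by NMF score (ties broken by
gene name). Every program is scored in every sample's tumor cells with an
expression-bin-controlled module score (24 equal-occupancy bins, 100 control
genes per set gene), program-score correlations are computed within each
sample and averaged across samples, and the programs are clustered by Ward
linkage on `1 - average correlation`. The number of clusters maximizes the
mean silhouette width (the cluster count is unstated in the source
analyses; a fixed cut is available). Clusters whose members cover less than
half of the samples are disregarded — coverage of exactly half is kept.
Meta-program signatures are the 100 genes with the highest average
max-scaled NMF score over member programs.

## The synthetic cohort

All validation runs on a generated cohort with planted ground truth, in
place of the multi-study patient data the method was developed on. The
generative model:

* Cells belong to (sample × cell type) strata: eight cell types (tumor,
  normal epithelium, and six stromal/immune types) across six samples in
  three cancer types, 2000 cells per sample by default.
* About one eighth of peaks are **marker peaks** carrying strong log-normal
  cell-type (sd 1.35), sample (sd 0.75) and stratum-interaction (sd 0.45)
  effects; the remaining peaks carry only weak structure (sd 0.1/0.06/0.08).
  Motif matches are placed outside the marker peaks, keeping motif sets
  free of the lineage-identity axis; peaks carry a synthetic GC covariate
  that tracks the marker (bias) class, which is what makes GC-matched
  background sampling meaningful on data without sequences.
  The marker peaks drive the LSI separation, so metacells are
  stratum-coherent, while the bulk of peaks stay noise-dominated at the
  metacell level. This split matters: if all peaks carried strong low-rank
  structure, null peak-gene correlations would live in a low-dimensional
  space, their z-scores would be noticeably lighter-tailed than normal, and
  the uniformity of null p-values — a property of the method we verify, not
  an accident — would fail by construction.
* Counts are Poisson given `rate = exp(intercept + effects) * depth`, with
  a global scale calibrated by root-finding so the expected nonzero
  fraction matches the configured sparsity (10% ATAC, 15% RNA); an optional
  gamma overdispersion knob exists. A `noise = "none"` mode emits expected
  counts for degenerate-limit tests.
* Each planted peak–gene link draws an independent latent factor over the
  48 strata, loaded identically by the distal peak, the gene and the gene's
  promoter peak. The loading is calibrated analytically from the
  metacell-level noise budget (stratum effects plus Poisson) with a fixed
  empirical attenuation constant compensating metacell impurity, so the
  realized grouped correlation matches `link_effect_size` (measured
  0.59–0.62 at a target of 0.6). Planted enhancers sit 30–120 kb from the
  TSS, the typical range of validated enhancer–promoter pairs and close
  enough that the distance-penalized co-accessibility to the promoter
  remains above the 0.2 cutoff.
* Tumor cells multiply the accessibility of peaks matched to the five true
  tumor motifs by `tf_activity_shift` (default 2), express the matching TF
  genes at the same fold change, and carry a planted footprint at those
  motif sites: fragment midpoints concentrate near the site (the binding
  shoulder) while insertions within ±10 bp are relocated outside the
  protected zone with probability `footprint_dip` (default 0.5).
* Each sample's tumor cells split over four expression programs of 100
  genes (log-effect 1.0), with 20% of tumor cells belonging to no program —
  transitional cells that give factorizations beyond the true rank nothing
  stable to model.
* Planted cancer-exclusive DARs add a log-effect of 1.5 for one cell type
  within one cancer type, and 5% of cells are "degraded" (diffuse fragment
  placement, low TSS enrichment) to exercise QC.

What passing tests on this cohort show: the statistics are implemented
correctly (oracle equivalences), the null calibration is honest (uniform
p-values under no planted signal), and each planted effect is recoverable
at its configured size with the published cutoffs. What they do not show:
robustness to sequence-dependent Tn5 bias, doublets, batch effects, copy
number variation, mappability artifacts, or annotation errors — none of
which the generator emulates — nor anything about effect sizes in real
tissue.

## Problem sizes and numerical choices

Validation cohorts use 2400 peaks over four chromosomes (50 kb spacing),
600 genes, 12,000 cells (two-sample, 300-peak cohorts in the unit tests),
and 200 metacells of 50 cells; these sizes keep every stage exact enough to
test while completing quickly. Graphical-lasso convergence is declared at a
relative off-diagonal change of 1e-4 (block coordinate descent, ridge 0.01
on the diagonal); zero-variance peaks are excluded per window; degenerate
nulls (zero trans standard deviation) and zero-variance correlation vectors
are errors and logged drops respectively; ties in iterative overlap merging
break by fold change then coordinates, and ties in signatures by gene name,
so all outputs are deterministic given seeds.
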