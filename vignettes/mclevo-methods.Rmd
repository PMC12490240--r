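---
title: "Methods: malignant B-cell identification and clonal evolution in MCL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: malignant B-cell identification and clonal evolution in MCL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mclevo)
```

# Scope

`mclevo` implements, as a tested and reusable pipeline, the computational
procedures used to dissect tumor heterogeneity and clonal evolution in
mantle cell lymphoma (MCL) from three data layers: single-cell RNA-seq,
single-cell B-cell-receptor (BCR) sequencing, and bulk whole-genome
sequencing (WGS). MCL is a B-cell malignancy whose hallmark is the
IGH–CCND1 translocation driving cyclin D1 overexpression; malignant cells
descend from a single transformed B cell, so they share one clonal BCR,
are restricted to a single immunoglobulin light chain (kappa or lambda),
overexpress *CCND1*, and carry somatic copy-number changes detectable in
their expression profiles. Those four properties are exactly the evidence
channels the malignant-cell classifier uses.

Because the patient data this class of study rests on are
access-restricted, the package ships a synthetic-cohort generator that
plants every quantity the pipeline is supposed to recover. All
quantitative validation in the test suite and in `scripts/acceptance.R`
is recovery of planted truth, plus exact checks of closed-form statistics
and independent brute-force oracles.

# Single-cell preprocessing

**QC.** Genes detected in fewer than 3 cells are removed; cells are kept
when they detect between 500 and 5,000 genes, have at most 40,000 total
counts, at most 20% mitochondrial counts, and at least 5% ribosomal
counts. Gene and cell filters are iterated to a fixed point so that
`apply_qc()` is idempotent — after filtering, every retained gene is still
detected in ≥3 retained cells. Mitochondrial and ribosomal genes are
recognized by symbol prefix (`MT-`, `RPL`/`RPS`). The ribosomal rule is
unusual in that it *keeps* high-ribosomal cells; it is implemented
verbatim and exposed as a parameter.

**Normalization.** Library-size log-normalization,
`log1p(count / total × 10^4)`. This is a deliberately simple stand-in for
variance-stabilizing transforms: the synthetic data have no batch
structure and no technology-specific mean–variance quirks, so nothing
downstream depends on a heavier normalization, and the simple form is
exactly scale-invariant and zero-preserving (both property-tested).

**Clustering.** Cells are embedded on the top 30 principal components
(fewer when rank-limited) of the z-scaled matrix, connected in a
shared-nearest-neighbor graph (k = 20), and partitioned by Louvain
modularity optimization at resolution 0.6. The embedding uses a truncated
SVD (`irlba`) and the SNN graph comes from `scran::buildSNNGraph`; both
are seeded, and labels are renumbered densely from 0 by decreasing size
so that runs are reproducible.

**Cell typing.** Each cluster is scored per marker set as the mean
z-scaled expression of the set's genes (B: *CD19*, *MS4A1*, *CD79A*; T:
*CD3D/E/G*; NK: *XCL2*, *NKG7*, *GNLY*; myeloid: *CD68*, *CD33*, *CST3*;
erythrocyte: *HBQ1*, *HBM*, *GYPA*) and assigned the argmax type; exact
ties fall back to the fixed order of the marker list with a warning.

**Differential expression.** Two-sided Wilcoxon rank-sum per gene
(`stats::wilcox.test`), Benjamini–Hochberg adjustment (`stats::p.adjust`).
Groups below 3 cells are refused. Type-I error calibration on homogeneous
synthetic data is part of the acceptance suite.

# BCR analysis

Contigs must be productive, full-length and high-confidence; a cell
enters clonotype analysis only with exactly one retained heavy and one
retained light chain (two productive heavy chains are ambiguous and
excluded). The clonotype key is the six-tuple of heavy/light V gene,
J gene and CDR3 peptide. A clonotype is *dominant* in a sample when it
covers strictly more than 5% of that sample's BCR-assigned cells; the
denominator can optionally be the total cell count instead, since either
reading is defensible and both appear in practice.

Somatic hypermutation (SHM) is counted position-wise against the
germline IGHV nucleotide sequence; `N` positions are excluded from both
numerator and denominator, and unequal lengths are resolved by a gap-free
sliding alignment that maximizes identity. The stored germline reference
in the generator is a synthetic 300-nt stand-in, not a database allele.

The light-chain ratio is `IGKC / (IGKC + max(IGLC1..IGLC7))` on raw
counts (summed within a cluster when used at cluster level); it is `NA`
when every immunoglobulin constant gene is zero, never 0/0. Values near
1 mean kappa restriction, near 0 lambda restriction; a mixed normal
population sits near the middle with a large spread.

# Expression-inferred CNV

Per gene, the log-space reference mean is subtracted; residuals are
clipped at ±3 pooled reference standard deviations, smoothed by a
centered moving average of 51 genes within each chromosome (shrinking at
edges), re-centered per cell at the median, and exponentiated to a ratio
around 1. Immunoglobulin genes are excluded first, because clonal
immunoglobulin expression mimics copy-number change — the same reason the
WGS side ignores immunoglobulin loci.

Two choices matter and are parameters:

* **Reference.** The pipeline uses the *normal-B* cells (provisionally
  identified from the absence of a dominant clonotype) as reference, not
  T/NK cells. A lineage-mismatched reference imprints the reference
  type's signature genes on every profile as spurious segments; a
  lineage-matched reference cancels them.
* **Denoising.** Smoothed residuals within 1.5 standard deviations of
  the reference cells' own smoothed residuals are set to zero. Without
  this step the per-cell noise floor at realistic sequencing depth is
  wider than the ±5% scoring band, and the genome-wide CNV score
  saturates for every cell; with it, the score counts genes with signal
  above the reference noise. `denoise = FALSE` recovers raw ratios
  (and `window = 1` then reduces to per-gene ratios exactly).

The **CNV score** is the verbatim count of genes with smoothed ratio
below 0.95 or above 1.05, genome-wide or within a region. **Segment
detection** additionally requires, per gene, that at least half the cells
are out of band in the same direction before calling a gain/loss run of
≥30 consecutive genes: a true copy-number change shifts the bulk of the
tumor, whereas subclone- or program-specific expression differences shift
a minority, and the majority rule suppresses them. **WGS concordance**
compares per-gene direction calls (expression band vs. segments at ≥2.3
or ≤1.7 copies) over genes covered by non-neutral WGS segments.

# Malignant-cell classification

Per B subcluster (the B compartment is re-clustered at resolution 1.0,
finer than the major clustering, so small normal-B populations separate),
four evidence channels are computed:

1. dominant-clonotype fraction among BCR-assigned cells (threshold 0.5);
2. light-chain consistency: |mean ratio − 0.5| ≥ 0.3 and SD ≤ 0.15;
3. *CCND1* log2 fold-change ≥ 1 against the normal-B reference;
4. median CNV score above the normal-B 95th percentile.

A cluster is **malignant** when channels 1–3 agree and channel 4
confirms; CNV disagreement demotes to **ambiguous** (CNV is
cross-validation and never promotes). A cluster with no positive primary
channel is **normal**; anything else is ambiguous, and ambiguous
clusters are exposed rather than forced. All four thresholds are package
defaults operationalizing criteria that are qualitative in the
literature; each is a parameter.

**Doublets.** T+B doublet clusters are flagged when both the B-marker
and T-marker scores exceed their cohort anchors. The anchor for each
marker set is the median per-cell score among cells *outside that set's
own lineage* (B markers over non-B cells, T markers over non-T cells),
and the cluster statistic is the median cell score. This is the
operational form of "both marker sets above the cohort median" that
remains meaningful when B cells are the majority of the dataset — an
unconditional cohort median of a B-marker score in a B-dominated tumor
sample sits inside the B population and would be uninformative.

# Expression programs

Per sample, consensus non-negative matrix factorization is run on the
malignant cells over the most variable genes. The input is z-scaled
normalized expression with negatives clipped at zero; the solver is
multiplicative-update NMF under the Frobenius objective, written in the
package (no NMF solver is among the dependencies, and the solver choice
is documented as a divergence from consensus-NMF tooling whose internals
differ). For each K in the range, `n_restarts` random initializations
are run; the consensus matrix holds the fraction of restarts co-assigning
two cells to the same maximum-usage program, and the cophenetic
coefficient correlates consensus distances with the cophenetic distances
of their average-linkage dendrogram. K* is the K just before the first
strict decrease of the cophenetic coefficient (ties do not trigger; a
never-decreasing profile returns the largest K with a warning — the
alternative "K at the decrease" reading is one line to change and is
deliberately not the default).

Programs are summarized by their 30 top-scoring genes. Meta-programs
cluster all programs across samples by shared-top-gene count
(distance = 30 − shared, average linkage) with the tree cut so that
programs sharing ≥3 genes can merge; the cut height is a parameter since
no canonical value exists. Meta-program scores are mean normalized
expression over the consensus set; paired samples are compared by a
two-sided Wilcoxon signed-rank test on per-gene sample means.

Default scale in the pipeline: K ∈ 2..5, 8 restarts, 200 variable genes,
100 iterations per fit. These are the package's desk-scale defaults —
`run_consensus_nmf()` itself defaults to K ∈ 2..10 and accepts any
restart count.

# Similarity index

For two samples of one patient, malignant cells are pooled and jointly
subclustered; each sample's composition vector over the joint subclusters
is compared by SI = Σ_k min(f_A(k), f_B(k)). SI < 0.35 is low and
SI > 0.67 high (both edges strict, so the boundary values are
intermediate). The identity 1 − SI = ½‖f_A − f_B‖₁ is used as an
independent oracle in the tests. Pooled joint clustering is batch-naive
by design: the generator plants no batch structure.

# Somatic-variant cascade

Variants keyed by (chrom, pos, ref, alt) are retained when called by at
least two of the per-caller tables. The germline-panel filter drops a
variant present (any high-quality alt read) in ≥ ceil(0.3·N) of N panel
samples; with the default 10-sample panel this is the 3-of-10 reading of
the "more than 30% (3/10)" rule, whose prose and parenthetical conflict —
the parenthetical wins by default and a strict mode implements the prose.
Paired-sample rescue re-labels a timepoint-specific variant as shared
when the partner sample's pileup shows any alt read; a specific status is
confirmed only when partner coverage exceeds 2 total high-quality reads,
otherwise the variant is unassessable (never dropped). Gene-level filters
drop variants in genes with gene damage index (GDI) above 2000 — except
*ATM*, a well-established MCL tumor suppressor — and in genes with mean
bulk FPKM below 0.5 (strict). A gene is reportable when nonsilently
mutated in ≥2 patients or in ≥1 patient while on a curated
known-lymphoma-gene list. WGS segments are amplified at ≥2.3 copies and
deleted at ≤1.7 (inclusive); segments overlapping immunoglobulin loci are
removed. Every stage logs the keys it keeps, the trail is replayable, and
no stage ever adds a variant key.

# Clonal evolution

The cancer cell fraction of a mutation is

  CCF = VAF · (p·CN + (1 − p)·2) / (p·m),

clipped to [0, 1], with purity p, local total copy number CN and
multiplicity m (default 1; estimable as round(VAF·CN/p) clipped to
[1, CN]). This explicit closed form replaces a richer purity/ploidy
model on the grounds that purity and local copy number enter the
pipeline as inputs.

Variants are clustered across samples by a binomial mixture: variant i
in cluster k has alt_is ~ Binomial(depth_is, φ_ks · f_is), with f the
purity/copy-number factor above. EM with a kmeans-on-naive-CCF start
plus random restarts; K is chosen by BIC over 1..K_max; the E-step
log-likelihood trace is retained and checked non-decreasing in the
tests. Binomial (not beta-binomial) emissions are a documented
simplification; overdispersion is the natural extension.

Clone trees are enumerated exhaustively over rooted topologies (root =
founder = highest mean CCF in the earliest sample, ties to the larger
cluster). A tree survives when, in every sample, each node's CCF + ε is
at least the sum of its children's CCFs, and no child exceeds its parent
by more than ε (ε = 0.05, the common sum-rule tolerance; comparisons
carry a 10⁻⁹ guard so boundary sums do not depend on floating-point
formulation). Survivors are ranked by ascending residual slack — the
unexplained CCF summed over internal nodes — so the tightest topology
ranks first. The enumeration is verified against an independent
Prüfer-sequence brute force in the tests. The fishplot export writes each
clone's CCF (which already nests descendants under the sum rule) per
timepoint in percent.

# Ligand–receptor interactions

The interaction statistic for a pair between a sender and receiver type
is the average of the mean ligand expression in the sender and the mean
receptor expression in the receiver; complexes take the minimum over
subunits, and expressed fractions are raw-count nonzero fractions,
minimum over subunits. The null permutes the cell-type labels across all
cells; p = (1 + #{null ≥ observed}) / (1 + n_perm) with 1,000
permutations by default, so p is never 0. Reported interactions need
p < 0.05, both expressed fractions > 10%, and membership on a curated
immune-related list. Null p-value uniformity is checked by a
Kolmogorov–Smirnov test in the acceptance suite.

# The synthetic cohort

The default configuration is the study condition the package is
validated under: 3 longitudinal samples × 2,000 cells × 2,000 genes;
cell-type mixture 48% malignant B, 6% normal B, 28% T, 10% NK, 8%
myeloid (tumor-sample-like, with B cells just under half so that
lineage-restricted markers have an informative background); shared-
dispersion negative-binomial counts (size 2) with lognormal library-size
factors; 8-fold signatures on ~50 genes per cell type; 4-fold *CCND1* in
malignant cells; kappa restriction for both planted clonotypes (0 and 2
SHM against the stored synthetic germline IGHV); a 2.0× gain of 120
genes and a 0.5× loss of 100 genes acting multiplicatively on the NB
mean; three malignant expression programs (40 genes, 3-fold); a 4-clone
tree with per-sample CCFs (founder plus a chain and a branch, chosen so
exactly one topology satisfies the sum rule); purity 0.7, WGS depth 200;
five callers at 0.9 sensitivity and 10⁻⁶/bp false positives; a 10-sample
germline panel with 5 systematic artifacts (4/10 panel hits) and 2 weak
ones (2/10); and planted QC failures (2% low-complexity, 2%
high-mitochondrial, 3% T+B doublets formed by summing two draws).
Normal B cells carry a 30-gene naive/memory-like feature set of their
own, mirroring how nonmalignant B subclusters separate from tumor cells
in real data.

What the generator does **not** emulate: batch effects and ambient RNA,
gene–gene correlation beyond the planted block structure, UMI
saturation, allele-specific copy number, subclonal CNV–expression
coupling beyond clone-segment assignment, structural-variant breakpoints
(IGH–CCND1 enters as an annotation), and read-level errors. Passing the
recovery suite therefore demonstrates that the implementations are
correct and calibrated on data matching their own assumptions — not that
the thresholds transfer unchanged to any real dataset.

# Problem sizes and determinism

The acceptance experiments use the default cohort (≈6,000 cells before
QC, 40 variants, depth 200), a 10-seed NMF model-selection experiment at
240 cells × 300 genes, type-I calibration at 1,000 cells × 500 genes,
and 200 permutation-null pairs at 199 permutations each — sizes chosen so
the whole validation runs comfortably on a laptop CPU. Every stochastic
stage takes an explicit seed, derives stream-specific sub-seeds from it,
and restores the caller's RNG state, so identical inputs give
byte-identical outputs; the determinism criterion is asserted on
serialized pipeline output in the tests.

# Known limitations

* Cluster-level classification: a malignant call is per subcluster, so a
  normal cell inside a malignant cluster inherits its label (the
  granularity is controlled by `subcluster_resolution`).
* Binomial CCF emissions understate read-count dispersion at high depth.
* Exhaustive tree enumeration is bounded at 10 clusters.
* The NMF solver is a plain multiplicative-update implementation;
  very ill-conditioned inputs may need more restarts.
* The doublet flag only detects T+B doublet *clusters*; isolated
  doublets inside a large cluster are not flagged (they are, however, a
  configured and measured part of the generator's truth).
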