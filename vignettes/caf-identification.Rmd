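---
title: "Identifying cancer-associated fibroblasts in glioblastoma scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cancer-associated fibroblasts in glioblastoma scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Glioblastoma was long assumed to lack cancer-associated fibroblasts (CAFs)
because the brain has no resident fibroblasts. Identifying the rare
CAF-like cells in glioblastoma single-cell RNA-seq therefore cannot rely on
a single positive marker. `cafid` implements a composite strategy:

1. **Quality control** of the count matrix (mitochondrial fraction, UMI
   depth) and global-scaling log normalization.
2. A **kernel-based CAF probability score** combining evidence *for* nine
   fibroblast markers (ACTA2, FAP, PDGFRA, PDGFRB, PDPN, S100A4, TNC, VIM,
   COL1A1) with evidence *against* five markers of the non-CAF stromal
   populations that most resemble CAFs: immune cells (PTPRC), epithelial
   cells (EPCAM), endothelial cells (PECAM1) and pericytes (CSPG4, RGS5).
3. **Expression-based copy-number inference** to remove malignant cells,
   recognized by the glioblastoma hallmark genotype of chromosome 7 gain
   plus chromosome 10 loss, which can masquerade as high-scoring cells.
4. **Cell typing and composition**, plus an early/late CAF differentiation
   contrast.
5. **Ligand–receptor crosstalk** between bulk expression profiles and
   **spatial proximity analysis** on deconvolved spot maps, the two
   downstream readouts that connect CAFs to glioblastoma stem cells and
   the tumor microenvironment.

Every stage is backed by a synthetic-data generator that plants ground
truth, so the whole pipeline is testable end to end.

## The CAF probability score

For a cell with log-normalized expression $u_g$ of gene $g$, bandwidth
$h > 0$ and Gaussian kernel

$$k(u) = e^{-u^2 / 2h^2},$$

the score over a panel with positive set $x$ and negative set $y$
($n = |x| + |y|$ genes present in the matrix) is

$$p = \operatorname{clamp}_{[0,1]}\;
\frac{1}{n}\left[\sum_{g \in x}\bigl(1 - k(u_g)\bigr)
 + \sum_{g \in y} k(u_g)\right].$$

The kernel measures closeness to zero expression: a positive marker
contributes its degree of expression ($1-k$), a negative marker its degree
of absence ($k$). Every term lies in $[0,1]$, so $p$ is a mean of evidence
and the clamp is a formal safeguard, never active in practice.

Properties the test suite asserts numerically: $p$ is monotone increasing
in each positive marker and decreasing in each negative marker; as
$h \to \infty$, $p \to |y|/n$; as $h \to 0^+$, $p$ depends only on the
zero/nonzero pattern; for small panels $p$ agrees with a direct
transcription of the formula to $10^{-12}$.

**Bandwidth.** `h = 1.0` on the natural-log normalized scale. Detected
expression at the 10,000-count scaling typically sits at $u \gtrsim 1$,
so `h = 1` places the kernel's half-mass right at the detected/undetected
divide. It is exposed as a parameter.

**Missing panel genes** are dropped from both the sum and $n$ and
reported, keeping $p$ a mean of observed evidence rather than imputing.

**The astrocyte score** uses the same machinery with an all-positive
10-gene panel (GFAP, AQP4, SLC1A3, SLC1A2, S100B, ALDH1L1, GJA1, SOX9,
NDRG2, FGFR3) — a pragmatic stand-in for canonical astrocyte markers,
used only to check that high-CAF-score cells are not astrocytes.

**"High score"** has no canonical cutoff; `high_score_cutoff()` supports a
fixed value (default 0.6, the midpoint between the all-zero baseline
$5/14 \approx 0.36$ and saturation) or a quantile rule.

## QC boundary semantics

Cells are excluded when the mitochondrial fraction is *strictly above*
20%, or the UMI total is *strictly below* 200 or *strictly above* 20,000.
The boundary cells (exactly 20%, exactly 200 or 20,000 UMIs) are retained.
This reading is stated explicitly because an off-by-one here changes every
downstream count. Genes are never filtered. Mitochondrial genes are
identified by the `MT-` name prefix (configurable). Normalization is
`ln(1 + count * 10000 / total)`, preserving zeros and per-cell depth
invariance.

## Copy-number inference

The caller is deliberately minimal — windowed averaging, not segmentation:

1. Genes are assigned to fixed 1 Mb bins by start position (0-based,
   half-open).
2. Per cell, each bin's value is the mean log-normalized expression of its
   member genes; empty bins are dropped.
3. Bins are smoothed along each chromosome with a moving average spanning
   5 Mb of genomic position.
4. Bins are centered on a reference: by default the per-bin **median
   across all cells** (robust when a minority of cells carry events), or
   the per-bin **mean across a user-supplied known-diploid mask** (a
   trusted reference deserves the unbiased estimator).
5. Each cell is recentered by its genome-wide median, removing cell-level
   offsets from depth and detection-rate differences.

Smoothing *before* centering matters: raw single-gene bins take a few
discrete values whose median across cells is a poor location estimate;
smoothed values are near-continuous, so the per-bin median robustly tracks
the diploid baseline even with ~20% aneuploid cells in the pool.

A chromosome is called **gain** for a cell when at least 50% of its bins
exceed +0.15 (log-ratio), **loss** symmetrically below −0.15. These
thresholds are package choices (whole-chromosome events are large
targets); both are parameters. A cell is flagged malignant if and only if
chromosome 7 is called gain *and* chromosome 10 is called loss.

**Magnitude calibration.** The mean log-ratio understates $\ln(\text{fold})$
when per-gene relative expression is low: with $r$ the per-gene relative
expression after scaling to 10,000, $E[\ln(1+r X/\mu) ] - E[\ln(1 + r' X/\mu)]
\to \ln(r/r')$ only for $r \gg 1$. At a 2,000-gene universe $r \approx 5$
and a 1.5-fold gain reads as ≈ 0.35 rather than $\ln 1.5 = 0.41$; at a
300-gene universe ($r \approx 33$) the estimate is consistent. The
magnitude checks in the test suite therefore run on the compact universe;
whole-chromosome *calls* are robust to the shrinkage and are exercised at
the default universe.

## Cell typing

Labels are assigned by fixed precedence: (1) malignant on the CNV flag;
else detection (count ≥ 1) of (2) AIF1/PTPRC → myeloid, (3) OLIG1 →
oligodendrocyte, (4) PECAM1 → endothelial, (5) CSPG4/RGS5 → pericyte,
(6) EPCAM/CD3D → epithelial/immune; else (7) CAF if the score reaches the
cutoff; else (8) unassigned. Malignancy outranks everything because
CNV-positive cells must be removed from the high-score set; marker
detection outranks the score because negative selection precedes scoring.
"Expressed" means at least one UMI (`detect_min`), the least-assumption
reading of detection-based selection.

CAF differentiation stage is a two-signature contrast — mean log
expression of late markers (ACTA2, SRGN) minus early markers (EVA1B,
DDIT4) — replacing full pseudotime reconstruction, which is out of scope;
the sign of the contrast is the stage readout and the population summary
is the fraction of CAFs that are late-dominant.

## Crosstalk and spatial analysis

Crosstalk edges are database pairs (TSV of ligand–receptor columns; a
50-pair fixture ships with the package, any database in that format is
accepted) whose ligand exceeds 0.05 FPKM on the sender side *and* whose
receptor exceeds 10 read counts on the receiver side — both strict
inequalities, so boundary values are excluded. The ligand side is
quantified in FPKM and the receptor side in read counts; unit correctness
is the caller's contract. `bidirectional_maps()` applies the same rule in
both directions.

Proximity analysis defines source spots as the top decile of a cell
type's probability field (ties included), computes every spot's Euclidean
distance to the nearest source, bins distances into 20 equal-width bins,
and reports the mean target probability per bin. Empty bins are reported,
never interpolated. The spot-weighted mean of bin means equals the global
target mean exactly (a conservation law the tests assert to $10^{-9}$).
Spatial association between two cell types is the Pearson correlation of
their per-spot probability vectors.

## The synthetic-data generator

The generator emulates the statistical regime the pipeline assumes, with
every law parameterized:

* **Counts**: negative binomial with dispersion 0.5
  (variance $= \mu + 0.5\mu^2$), the standard overdispersed scRNA-seq
  model, keeping planted effects analytically checkable.
* **Depth**: log-normal, median 5,000 UMIs, log-sd 0.35.
* **Mitochondrial fraction**: Beta(2, 38) (mean 5%), allocated equally to
  13 `MT-` genes.
* **Gene universe**: 2,000 nuclear genes spread over the 22 autosomes in
  proportion to chromosome length (≈ 1 gene / 1.2 Mb). Named marker genes
  are embedded on chromosomes other than 7 and 10 so planted CNVs never
  touch a marker.
* **Populations**: multinomial cell labels (default 52% CAF, 22% myeloid,
  20% malignant, 6% oligodendrocyte, matching the composition reported
  for serially trypsinized glioblastoma cells). Each population
  *exclusively* expresses its catalog markers at 8× the baseline gene
  weight; catalog genes are silent in all other populations. Exclusivity
  is a deliberate idealization: detection-based negative selection and
  lineage labeling are only well-posed when a marker's off-population
  detection probability is near zero, which overdispersed counts at a
  shared baseline cannot deliver.
* **CNV**: malignant cells have chromosome 7 gene means ×1.5 and
  chromosome 10 means ×0.5.
* Per-gene means are relative weights normalized within each cell, so the
  expected total equals the drawn depth and the expected mitochondrial
  fraction equals the drawn Beta value.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, biological co-expression structure, or genuine astrocyte/CAF
transcriptional overlap. Passing tests demonstrate the pipeline's internal
correctness and its behavior under the planted regime — not performance on
real tissue, where marker leakage and continuous cell states blur every
margin used here.

Bulk crosstalk profiles are planted directly above/below/exactly at the
thresholds (exact planting requires database pairs with pairwise-distinct
genes, which the generator enforces). Spatial maps are mixtures of planar
Gaussian bumps on a unit-square grid, rescaled to $[0,1]$; colocalized
cell types share bump centers with independent amplitudes plus light
field noise.

## Numerical and design choices

* Multinomial labels are drawn with `rmultinom` plus a permutation rather
  than weighted `sample()`, whose alias method has a small, measurable
  bias at these sizes.
* Chromosome names are normalized by stripping a `chr` prefix;
  coordinates are 0-based half-open throughout.
* Tie handling: quantile-based source-spot selection and score cutoffs
  include ties (ties break toward flagging).
* Degenerate inputs are contracts, not crashes: zero-depth cells are
  flagged and always fail QC but are a named error in normalization;
  an all-coincident spot map collapses to a single proximity bin with a
  warning; a chromosome with one bin is called on that bin with a warning.
* Problem sizes in the tests: the study-scale run uses 5,000 cells ×
  2,013 genes (the deposited dataset's order of magnitude); the CNV
  magnitude check uses 1,500 cells × 300 genes (the high-coverage regime
  above); property tests use a few hundred cells.

## Known limitations

* The CNV caller does no segmentation and calls only whole chromosomes;
  arm-level or focal events are invisible by design.
* With the default all-cells median reference, a malignant fraction
  approaching 50% would drag the baseline; supply a known-diploid
  reference mask in that regime.
* The score treats panel genes symmetrically; no weighting by marker
  specificity.
* Crosstalk is a threshold filter, not a statistical test; it inherits
  whatever normalization the bulk profiles carry.
* Spatial distances are planar Euclidean on the supplied coordinates; no
  hex-grid adjacency or tissue geometry.
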