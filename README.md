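# cafid

Identification of cancer-associated fibroblasts (CAFs) in glioblastoma
single-cell RNA-seq.

The brain has no resident fibroblasts, so glioblastoma CAFs cannot be
called from any single marker. `cafid` identifies them by combining three
lines of evidence per cell:

1. a **kernel-based CAF probability score** — with Gaussian kernel
   `k(u) = exp(-u² / 2h²)` on log-normalized expression `u`, the score over
   a panel of positive markers `x` (ACTA2, FAP, PDGFRA, PDGFRB, PDPN,
   S100A4, TNC, VIM, COL1A1) and negative stromal markers `y` (PTPRC,
   EPCAM, PECAM1, CSPG4, RGS5) is

   `p = clamp₀₁ (1/n) [ Σ_{g∈x} (1 − k(u_g)) + Σ_{g∈y} k(u_g) ]`,

   crediting expression of CAF markers and absence of the non-CAF markers;
2. **negative selection** — cells detecting epithelial (EPCAM), endothelial
   (PECAM1), pericyte (CSPG4) or immune (PTPRC) transcripts are excluded;
3. **copy-number inference from expression** (1 Mb bins, 5 Mb moving
   average, reference centering) — cells with the glioblastoma hallmark
   genotype chr7 gain + chr10 loss are malignant, not CAFs, however high
   they score.

Around this core the package provides QC with strict boundary semantics
(mito fraction > 20%, UMI < 200 or > 20,000 excluded), cell typing with
composition summaries, an early/late CAF stage contrast (EVA1B/DDIT4 vs
ACTA2/SRGN), thresholded ligand–receptor crosstalk maps (ligand FPKM >
0.05 and receptor counts > 10, both strict), spatial proximity curves and
correlations on cell-type probability fields, and a fully parameterized
negative-binomial synthetic-data generator that plants ground truth for
every stage. See the vignette (`vignettes/caf-identification.Rmd`) for the
model details and design rationale.

## Worked example

Simulate a study-scale dataset (5,000 cells; 52% CAF, 22% myeloid, 20%
malignant, 6% oligodendrocyte) and run the full pipeline:

```r
library(cafid)

sim <- simulate_counts(simulation_config(seed = 1))
print(sim)
#> <sim_counts> 5000 cells x 2013 genes
#>             CAF       malignant         myeloid oligodendrocyte
#>            2601            1023            1093             283

report <- run_pipeline(list(simulate = list(seed = 1)))
#> [simulate] 5000 cells, seed 1
#> [qc] 4980/5000 cells retained
#> [score] median CAF probability 0.909
#> [cnv] 947 cells flagged chr7+/chr10-
#> [classify] CAF=0.52 malignant=0.19 myeloid=0.22 oligodendrocyte=0.06 unassigned=0.02
print(report)
#> <pipeline_report> cafid 0.1.0, seed 1
#>   cells: 4980
#>   composition:
#>     CAF                 52.0%
#>     malignant           19.0%
#>     myeloid             21.9%
#>     oligodendrocyte      5.6%
#>     unassigned           1.5%
#>   recovery: AUC 1.000, max composition error 0.010
#>   malignant flag: sens 0.928, spec 1.000
```

The report says: after QC, the CAF probability score separates planted
CAFs perfectly (AUC 1.0), the recovered cell-type fractions are within one
point of the planted truth, and the chr7+/chr10− flag finds 93% of
planted malignant cells with no false positives (with a known-diploid
reference mask instead of the blind all-cells median, sensitivity rises
to ~0.99).

Individual stages are plain functions (`read_counts`, `compute_cell_qc`,
`qc_filter`, `log_normalize`, `panel_probability`, `negative_selection`,
`bin_genes`, `infer_cnv`, `call_chromosome_events`, `is_gbm_malignant`,
`assign_labels`, `stage_scores`, `infer_crosstalk`, `proximity_curve`,
`spatial_correlation`, ...), and a thin command-line wrapper covering
them lives at `inst/cli/cafid.R`:

```sh
Rscript inst/cli/cafid.R simulate --n-cells 5000 --seed 1 --out simdir
Rscript inst/cli/cafid.R qc --in simdir --out qcdir
Rscript inst/cli/cafid.R score --in qcdir --panel caf --out scores.tsv
Rscript inst/cli/cafid.R pipeline --seed 1 --out outdir
```

`validate_against_accession()` recomputes the headline percentages
(negative-selection retention, marker prevalences, panel coverage,
composition) on a user-downloaded expression matrix — e.g. the deposited
GEO accession GSE132825 — and prints them beside the published reference
values; it never downloads anything itself.

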