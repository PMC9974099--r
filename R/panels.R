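#' Construct a marker panel
#'
#' A marker panel is a named set of positive marker genes and (optionally)
#' negative marker genes used by [panel_probability()]. Positive markers are
#' genes whose expression raises the score; negative markers are genes whose
#' absence raises it.
#'
#' @param name Panel name (e.g. `"CAF"`).
#' @param positives Character vector of positive marker gene symbols.
#' @param negatives Character vector of negative marker gene symbols
#'   (may be empty).
#' @return An object of class `marker_panel`: a list with elements `name`,
#'   `positives`, `negatives`.
#' @examples
#' marker_panel("demo", positives = c("ACTA2", "COL1A1"), negatives = "PTPRC")
#' @export
marker_panel <- function(name, positives, negatives = character()) {
  positives <- as.character(positives)
  negatives <- as.character(negatives)
  if (length(positives) == 0L)
    stop("a marker panel needs at least one positive gene", call. = FALSE)
  if (anyDuplicated(c(positives, negatives)))
    stop("positives and negatives must be disjoint and unique", call. = FALSE)
  structure(list(name = as.character(name)[1L],
                 positives = positives,
                 negatives = negatives),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", x$name, ": ", length(x$positives), " positive, ",
      length(x$negatives), " negative gene(s)\n", sep = "")
  cat("  +", paste(x$positives, collapse = ", "), "\n")
  if (length(x$negatives))
    cat("  -", paste(x$negatives, collapse = ", "), "\n")
  invisible(x)
}

#' Default marker panels for glioblastoma CAF identification
#'
#' The CAF panel scores cells on expression of 9 fibroblast-activation markers
#' (ACTA2, FAP, PDGFRA, PDGFRB, PDPN, S100A4, TNC, VIM, COL1A1) and on absence
#' of 5 markers of non-CAF stromal populations: immune cells (PTPRC),
#' epithelial cells (EPCAM), endothelial cells (PECAM1) and pericytes
#' (CSPG4, RGS5).
#'
#' The astrocyte panel is a 10-gene all-positive panel of canonical astrocyte
#' genes, used to confirm that high-CAF-score cells are not astrocytes.
#'
#' @return A list with elements `caf` and `astrocyte`, each a [marker_panel()].
#' @export
gbm_marker_panels <- function() {
  list(
    caf = marker_panel(
      "CAF",
      positives = c("ACTA2", "FAP", "PDGFRA", "PDGFRB", "PDPN",
                    "S100A4", "TNC", "VIM", "COL1A1"),
      negatives = c("PTPRC", "EPCAM", "PECAM1", "CSPG4", "RGS5")),
    astrocyte = marker_panel(
      "astrocyte",
      positives = c("GFAP", "AQP4", "SLC1A3", "SLC1A2", "S100B",
                    "ALDH1L1", "GJA1", "SOX9", "NDRG2", "FGFR3"))
  )
}

#' Default lineage detection markers
#'
#' Marker genes used by [assign_labels()] to call non-CAF lineages by simple
#' transcript detection: myeloid (AIF1, PTPRC), oligodendrocyte (OLIG1),
#' endothelial (PECAM1), pericyte (CSPG4, RGS5) and epithelial/immune
#' contaminants (EPCAM, CD3D).
#'
#' @return Named list mapping lineage label to character vector of genes.
#' @export
default_lineage_markers <- function() {
  list(
    myeloid          = c("AIF1", "PTPRC"),
    oligodendrocyte  = c("OLIG1"),
    endothelial      = c("PECAM1"),
    pericyte         = c("CSPG4", "RGS5"),
    epithelial_immune = c("EPCAM", "CD3D")
  )
}

#' Default population marker catalog for the simulator
#'
#' Maps each simulated population to the genes it exclusively expresses.
#' Genes in this catalog are silent in every other population, which is what
#' makes detection-based negative selection and lineage labeling well defined
#' on synthetic data. A gene may appear in exactly one population's list.
#'
#' @return Named list mapping population label to character vector of genes.
#' @export
default_marker_assignments <- function() {
  panels <- gbm_marker_panels()
  list(
    CAF              = c(panels$caf$positives, "SRGN"),
    malignant        = c("SOX2", "EGFR"),
    myeloid          = c("AIF1", "PTPRC"),
    oligodendrocyte  = c("OLIG1", "MOG"),
    endothelial      = c("PECAM1", "CD34"),
    pericyte         = c("CSPG4", "RGS5"),
    epithelial_immune = c("EPCAM", "CD3D"),
    astrocyte        = panels$astrocyte$positives
  )
}

# 13 protein-coding mitochondrial genes (Seurat-style "MT-" prefix)
mito_gene_names <- function(prefix = "MT-") {
  paste0(prefix, c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
                   "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"))
}

# approximate lengths (Mb) of the 22 human autosomes, used to spread the
# synthetic gene universe at roughly real chromosome proportions
.chr_mb <- c(248, 242, 198, 190, 181, 171, 159, 145, 138, 134, 135,
             133, 114, 107, 102, 90, 83, 80, 59, 64, 47, 51)

#' Build the synthetic gene universe annotation
#'
#' Spreads `n_genes` nuclear genes over the 22 autosomes in proportion to
#' approximate chromosome lengths, evenly spaced along each chromosome
#' (about 1 gene per 1.2 Mb at the default 2,000 genes), then appends 13
#' mitochondrial genes (prefix `MT-`, chromosome `"MT"`). Named marker genes
#' replace filler gene ids at their assigned slots on chromosomes other than
#' 7 and 10, so copy-number effects planted on chromosomes 7/10 never touch a
#' marker gene.
#'
#' @param n_genes Number of nuclear genes (>= 200).
#' @param named_genes Character vector of real gene symbols to embed in the
#'   universe; defaults to all panel, lineage and stage genes used elsewhere
#'   in the package.
#' @return `data.frame` with columns `gene`, `chromosome`, `start`
#'   (0-based bp).
#' @export
gene_universe <- function(n_genes = 2000, named_genes = NULL) {
  if (n_genes < 200) stop("n_genes must be at least 200", call. = FALSE)
  if (is.null(named_genes)) {
    named_genes <- unique(c(
      unlist(default_marker_assignments(), use.names = FALSE),
      "EVA1B", "DDIT4"))
  }
  per_chr <- round(n_genes * .chr_mb / sum(.chr_mb))
  # fix rounding drift on the largest chromosome
  per_chr[1L] <- per_chr[1L] + (n_genes - sum(per_chr))
  chrom <- rep(as.character(seq_len(22L)), per_chr)
  start <- unlist(lapply(seq_len(22L), function(i) {
    k <- per_chr[i]
    spacing <- .chr_mb[i] * 1e6 / (k + 1)
    round(spacing * seq_len(k))
  }), use.names = FALSE)
  gene <- sprintf("GENE%04d", seq_len(n_genes))
  # embed named genes on chromosomes away from the planted CNV (chr7/chr10),
  # spread deterministically across eligible slots
  eligible <- which(!(chrom %in% c("7", "10")))
  if (length(named_genes) > length(eligible))
    stop("gene universe too small for the named marker set", call. = FALSE)
  slots <- eligible[round(seq(1L, length(eligible),
                              length.out = length(named_genes)))]
  gene[slots] <- named_genes
  ann <- data.frame(gene = c(gene, mito_gene_names()),
                    chromosome = c(chrom, rep("MT", 13L)),
                    start = c(start, round(seq(0, 15000, length.out = 13L))),
                    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann
}
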