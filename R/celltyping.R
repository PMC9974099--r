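#' Assign per-cell type labels
#'
#' Combines CNV malignancy flags, lineage-marker detection and the CAF
#' probability score into one label per cell, applying a fixed precedence:
#' (1) `malignant` on the CNV flag; else (2) `myeloid` if AIF1 or PTPRC is
#' detected; (3) `oligodendrocyte` if OLIG1; (4) `endothelial` if PECAM1;
#' (5) `pericyte` if CSPG4 or RGS5; (6) `epithelial_immune` if EPCAM or CD3D;
#' else (7) `CAF` if the score reaches `cutoff`; else (8) `unassigned`.
#' Malignancy outranks everything because CNV-positive cells are removed from
#' the high-score set; marker detection outranks the score because negative
#' selection precedes scoring.
#'
#' @param m Cells x genes count matrix (for marker detection).
#' @param scores A `score_result` from [panel_probability()] on the same
#'   cells.
#' @param malignant Logical per-cell CNV flag from [is_gbm_malignant()], or
#'   `NULL` to skip the malignant rule (e.g. when no CNV stage was run).
#' @param lineage_markers Named list mapping label to detection genes;
#'   default [default_lineage_markers()].
#' @param cutoff CAF score cutoff (default 0.6).
#' @param detect_min Minimal count that counts as detection (default 1).
#' @return `data.frame` of class `celltype_calls` with columns `cell`,
#'   `label`, `p`, `malignant`.
#' @export
assign_labels <- function(m, scores, malignant = NULL,
                          lineage_markers = default_lineage_markers(),
                          cutoff = 0.6, detect_min = 1L) {
  validate_count_matrix(m)
  stopifnot(inherits(scores, "score_result"))
  if (!identical(scores$scores$cell, rownames(m)))
    stop("scores do not match the matrix cells", call. = FALSE)
  if (is.null(malignant)) {
    malignant <- rep(FALSE, nrow(m))
  } else {
    malignant <- malignant[rownames(m)]
    if (any(is.na(malignant)))
      stop("malignant flags do not cover all cells", call. = FALSE)
  }
  label <- rep("unassigned", nrow(m))
  assigned <- rep(FALSE, nrow(m))
  label[malignant] <- "malignant"
  assigned <- assigned | malignant
  for (lin in names(lineage_markers)) {
    genes <- intersect(lineage_markers[[lin]], colnames(m))
    if (!length(genes)) {
      warning("lineage markers absent from matrix, rule skipped: ", lin,
              call. = FALSE)
      next
    }
    hit <- Matrix::rowSums(m[, genes, drop = FALSE] >= detect_min) > 0
    sel <- !assigned & hit
    label[sel] <- lin
    assigned <- assigned | sel
  }
  caf <- !assigned & scores$scores$p >= cutoff
  label[caf] <- "CAF"
  data.frame(cell = rownames(m), label = label, p = scores$scores$p,
             malignant = unname(malignant), stringsAsFactors = FALSE) |>
    structure(class = c("celltype_calls", "data.frame"))
}

#' Cell-type composition
#'
#' @param calls A `celltype_calls` table from [assign_labels()], or any
#'   character vector of labels.
#' @return List of class `composition` with `fractions` (over all cells),
#'   `fractions_assigned` (excluding `unassigned`), and `n_cells`.
#' @export
composition_summary <- function(calls) {
  labels <- if (is.data.frame(calls)) calls$label else as.character(calls)
  if (!length(labels)) stop("no cells to summarize", call. = FALSE)
  tab <- table(labels)
  fr <- as.numeric(tab) / length(labels)
  names(fr) <- names(tab)
  keep <- names(tab) != "unassigned"
  fr_a <- if (any(keep)) {
    a <- as.numeric(tab[keep]) / sum(tab[keep])
    names(a) <- names(tab)[keep]
    a
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(fractions = fr, fractions_assigned = fr_a,
                 n_cells = length(labels)),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> n =", x$n_cells, "cells\n")
  fr <- sort(x$fractions, decreasing = TRUE)
  for (lbl in names(fr))
    cat(sprintf("  %-18s %5.1f%%\n", lbl, 100 * fr[lbl]))
  invisible(x)
}

#' Early- versus late-stage CAF signature scores
#'
#' Scores each cell on an early-stage signature (default EVA1B, DDIT4) and a
#' late-stage signature (default ACTA2, SRGN) as the mean log-normalized
#' expression of each gene set; the stage ratio `late - early` (log scale) is
#' positive for cells resembling fully differentiated CAFs. The summary
#' reports the fraction of CAFs with late > early.
#'
#' @param norm Log-normalized cells x genes matrix.
#' @param caf_mask Logical mask of CAF cells (default: all cells).
#' @param early_genes,late_genes Signature gene sets.
#' @return `data.frame` with columns `cell`, `early`, `late`, `stage_ratio`;
#'   attribute `"fraction_late_dominant"` gives the summary over `caf_mask`.
#' @export
stage_scores <- function(norm, caf_mask = NULL,
                         early_genes = c("EVA1B", "DDIT4"),
                         late_genes = c("ACTA2", "SRGN")) {
  eg <- intersect(early_genes, colnames(norm))
  lg <- intersect(late_genes, colnames(norm))
  if (!length(eg)) stop("no early-stage gene present", call. = FALSE)
  if (!length(lg)) stop("no late-stage gene present", call. = FALSE)
  early <- Matrix::rowMeans(norm[, eg, drop = FALSE])
  late <- Matrix::rowMeans(norm[, lg, drop = FALSE])
  out <- data.frame(cell = rownames(norm), early = unname(early),
                    late = unname(late),
                    stage_ratio = unname(late - early),
                    stringsAsFactors = FALSE)
  if (is.null(caf_mask)) caf_mask <- rep(TRUE, nrow(out))
  frac <- if (any(caf_mask)) mean(out$stage_ratio[caf_mask] > 0) else NA_real_
  attr(out, "fraction_late_dominant") <- frac
  out
}
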