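#' Per-cell quality-control metrics
#'
#' Computes each cell's total UMI count and mitochondrial fraction
#' (counts in genes whose name starts with `mito_prefix`, divided by the
#' total). Cells with zero total counts get `mito_fraction = NA` and are
#' flagged; they always fail [qc_filter()].
#'
#' @param m Cells x genes count matrix.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return `data.frame` with columns `cell`, `total_umi`, `mito_fraction`,
#'   `zero_depth`.
#' @examples
#' m <- Matrix::Matrix(matrix(c(30, 70), 1, dimnames = list("c1", c("MT-CO1", "ACTA2"))),
#'                     sparse = TRUE)
#' compute_cell_qc(m)
#' @export
compute_cell_qc <- function(m, mito_prefix = "MT-") {
  validate_count_matrix(m)
  total <- Matrix::rowSums(m)
  mito_genes <- startsWith(colnames(m), mito_prefix)
  mito <- if (any(mito_genes)) {
    Matrix::rowSums(m[, mito_genes, drop = FALSE])
  } else {
    rep(0, nrow(m))
  }
  frac <- ifelse(total > 0, mito / total, NA_real_)
  data.frame(cell = rownames(m), total_umi = as.integer(round(total)),
             mito_fraction = frac, zero_depth = total == 0,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' Retains exactly the cells with `mito_fraction <= mito_max` and
#' `umi_min <= total_umi <= umi_max`. All exclusions are strict readings of
#' the stated cutoffs: mitochondrial percentage strictly above 20% excludes,
#' fewer than 200 or more than 20,000 UMIs exclude, so the boundary values
#' 200, 20,000 and exactly 20% are retained. Genes are never filtered.
#'
#' @param m Cells x genes count matrix.
#' @param qc QC table from [compute_cell_qc()] on the same matrix.
#' @param mito_max Maximum tolerated mitochondrial fraction (default 0.20).
#' @param umi_min,umi_max Inclusive UMI bounds (defaults 200 and 20,000).
#' @return The filtered matrix. Attribute `"qc_summary"` carries the number
#'   of cells removed per criterion (a cell can count toward several).
#' @export
qc_filter <- function(m, qc, mito_max = 0.20, umi_min = 200,
                      umi_max = 20000) {
  validate_count_matrix(m)
  if (!identical(qc$cell, rownames(m)))
    stop("qc table does not match the matrix cells", call. = FALSE)
  fail_mito <- !qc$zero_depth & qc$mito_fraction > mito_max
  fail_low <- qc$total_umi < umi_min
  fail_high <- qc$total_umi > umi_max
  fail_zero <- qc$zero_depth
  keep <- !(fail_mito | fail_low | fail_high | fail_zero)
  if (!any(keep))
    warning("all cells removed by QC", call. = FALSE)
  out <- m[keep, , drop = FALSE]
  attr(out, "qc_summary") <- c(n_input = nrow(m), n_retained = sum(keep),
                               removed_mito = sum(fail_mito),
                               removed_low_umi = sum(fail_low),
                               removed_high_umi = sum(fail_high),
                               removed_zero_depth = sum(fail_zero))
  out
}

#' Log-normalize a count matrix
#'
#' Global-scaling log normalization: each cell's counts are scaled to a
#' common total (`scale`, default 10,000) and transformed as
#' `ln(1 + count * scale / total)`. Zero counts map to exactly zero, so
#' sparsity is preserved; the result is invariant to uniform rescaling of a
#' cell's depth.
#'
#' @param m Cells x genes count matrix; every cell must have positive total.
#' @param scale Target per-cell total (default 10,000).
#' @return Sparse `dgCMatrix` of normalized values (natural-log scale).
#' @examples
#' m <- Matrix::Matrix(matrix(c(100, 9900), 1,
#'                     dimnames = list("c1", c("g1", "g2"))), sparse = TRUE)
#' log_normalize(m)[1, "g1"]  # ln(101) = 4.61512
#' @export
log_normalize <- function(m, scale = 10000) {
  validate_count_matrix(m)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  total <- Matrix::rowSums(m)
  if (any(total == 0))
    stop("zero-depth cell(s) present: ",
         paste(utils::head(rownames(m)[total == 0], 5), collapse = ", "),
         call. = FALSE)
  norm <- Matrix::Matrix(m, sparse = TRUE)
  norm@x <- log1p(norm@x * scale / total[norm@i + 1L])
  norm
}
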