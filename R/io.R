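#' Read a cells x genes count matrix
#'
#' Accepts either a 10x-style triplet directory (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv`, as written by [write_counts_10x()]) or a
#' dense TSV with gene rows (first column gene id, header row of cell ids).
#' Counts must be nonnegative integers; the matrix is returned with cells as
#' rows and genes as columns, in file order.
#'
#' @param path Directory containing the triplet files, or a dense TSV file.
#' @return Sparse `dgCMatrix`, cells x genes, with cell/gene dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) {
      if (!file.exists(f))
        stop("missing triplet file: ", f, call. = FALSE)
    }
    m <- Matrix::readMM(mtx)             # genes x cells on disk (10x layout)
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
      stop("matrix.mtx dimensions (", nrow(m), " x ", ncol(m),
           ") do not match features.tsv (", nrow(features),
           ") / barcodes.tsv (", length(barcodes), ")", call. = FALSE)
    x <- m@x
    if (any(x < 0) || any(x != round(x)))
      stop("counts must be nonnegative integers", call. = FALSE)
    m <- Matrix::t(m)
    dimnames(m) <- list(barcodes, features[[1]])
  } else if (file.exists(path)) {
    tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    dense <- as.matrix(tab)
    if (!is.numeric(dense) || any(is.na(dense)))
      stop("dense TSV must be numeric with no missing values", call. = FALSE)
    if (any(dense < 0) || any(dense != round(dense)))
      stop("counts must be nonnegative integers", call. = FALSE)
    m <- Matrix::t(Matrix::Matrix(dense, sparse = TRUE))
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  validate_count_matrix(m)
  methods::as(m, "CsparseMatrix")
}

validate_count_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs cell and gene names", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene identifiers", call. = FALSE)
  invisible(m)
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, integer, genes x cells),
#' `features.tsv` (gene id, gene name, and — when an annotation is supplied —
#' chromosome and start), `barcodes.tsv`, and optionally `labels.tsv`
#' (barcode, label). Round-trips losslessly through [read_counts()].
#'
#' @param m Cells x genes count matrix (`dgCMatrix` or dense).
#' @param dir Output directory (created if needed).
#' @param annotation Optional `data.frame` (gene, chromosome, start) written
#'   into `features.tsv`.
#' @param labels Optional named character vector of per-cell labels.
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(m, dir, annotation = NULL, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- Matrix::t(Matrix::Matrix(m, sparse = TRUE))
  Matrix::writeMM(gm, file.path(dir, "matrix.mtx"))
  feats <- data.frame(id = colnames(m), name = colnames(m),
                      stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    idx <- match(colnames(m), annotation$gene)
    feats$chromosome <- annotation$chromosome[idx]
    feats$start <- annotation$start[idx]
  }
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(barcode = rownames(m), label = labels[rownames(m)]),
      file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene`, `chromosome`, `start` (0-based bp).
#' @return `data.frame` with those three columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "start")
  if (!all(need %in% names(ann)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$gene))
    stop("duplicate genes in annotation", call. = FALSE)
  ann$chromosome <- as.character(ann$chromosome)
  ann[need]
}
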