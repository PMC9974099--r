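# strip an optional "chr" prefix so "chr7" and "7" name the same chromosome
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  has_prefix <- grepl("^chr", chrom, ignore.case = TRUE)
  if (any(has_prefix) && !all(has_prefix))
    warning("mixed chromosome naming (chr7 vs 7); 'chr' prefix stripped",
            call. = FALSE)
  sub("^chr", "", chrom, ignore.case = TRUE)
}

#' Partition genes into fixed-width genomic bins
#'
#' Assigns every annotated gene to a fixed-width bin on its chromosome by
#' start position (0-based, half-open intervals: a gene at exactly
#' `bin_size` falls in the second bin). Bins with no genes are dropped.
#'
#' @param annotation `data.frame` with columns `gene`, `chromosome`, `start`.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return `data.frame` of class `genomic_bins` with columns `bin`
#'   (`chrom:start-end`), `chromosome`, `start`, `end`, `n_genes`, and a
#'   list-column `genes`; ordered by chromosome and start.
#' @export
bin_genes <- function(annotation, bin_size = 1e6) {
  if (!nrow(annotation)) stop("empty annotation", call. = FALSE)
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  chrom <- normalize_chrom(annotation$chromosome)
  idx <- floor(annotation$start / bin_size)
  key <- paste(chrom, idx, sep = "\r")
  split_genes <- split(annotation$gene, key)
  parts <- strsplit(names(split_genes), "\r", fixed = TRUE)
  out <- data.frame(
    chromosome = vapply(parts, `[`, "", 1L),
    start = vapply(parts, function(p) as.numeric(p[2L]), 0) * bin_size,
    stringsAsFactors = FALSE)
  out$end <- out$start + bin_size
  out$n_genes <- lengths(split_genes)
  out$genes <- unname(split_genes)
  # order: numeric chromosomes first in numeric order, then others
  suppress <- function(x) suppressWarnings(as.numeric(x))
  ord <- order(is.na(suppress(out$chromosome)), suppress(out$chromosome),
               out$chromosome, out$start)
  out <- out[ord, , drop = FALSE]
  out$bin <- sprintf("%s:%.0f-%.0f", out$chromosome, out$start, out$end)
  rownames(out) <- NULL
  structure(out[, c("bin", "chromosome", "start", "end", "n_genes", "genes")],
            class = c("genomic_bins", "data.frame"))
}

# position-based moving average within each chromosome: each bin is replaced
# by the mean of bins whose midpoints lie within span/2 of its own
smooth_bins <- function(B, bins, smooth_span) {
  half <- smooth_span / 2
  mid <- (bins$start + bins$end) / 2
  for (chr in unique(bins$chromosome)) {
    j <- which(bins$chromosome == chr)
    if (length(j) == 1L) next
    S <- outer(mid[j], mid[j], function(a, b) abs(a - b) <= half)
    S <- S / rowSums(S)
    B[, j] <- B[, j, drop = FALSE] %*% t(S)
  }
  B
}

#' Infer smoothed per-cell copy-number profiles from expression
#'
#' For each cell, each bin's value is the mean log-normalized expression of
#' its member genes; bins are smoothed along each chromosome with a moving
#' average spanning `smooth_span` bp, centered by subtracting a reference
#' value (the per-bin mean across a trusted reference mask, or the robust
#' per-bin median across all cells when `reference = "median"`), and finally
#' recentered per cell by the
#' cell's genome-wide median (removing cell-level offsets from depth and
#' detection-rate differences). The result approximates a per-bin log-ratio
#' relative to the reference: positive for gains, negative for losses.
#' Whole-chromosome events are assumed to cover a minority of both the cells
#' (so the per-bin median is a diploid baseline) and the genome (so the
#' per-cell median is anchored by unaffected chromosomes).
#'
#' @param norm Log-normalized cells x genes matrix.
#' @param bins Bins from [bin_genes()].
#' @param smooth_span Moving-average span in bp (default 5 Mb).
#' @param reference `"median"` (all cells) or a logical/character mask of
#'   known-diploid reference cells.
#' @return A `cnv_profile`: list with `log_ratio` (dense cells x bins
#'   matrix), `bins`, `reference_description`.
#' @export
infer_cnv <- function(norm, bins, smooth_span = 5e6, reference = "median") {
  stopifnot(inherits(bins, "genomic_bins"))
  if (max(table(bins$chromosome)) < 2)
    stop("need at least 2 bins on some chromosome", call. = FALSE)
  gene_ok <- lapply(bins$genes, intersect, colnames(norm))
  if (!any(lengths(gene_ok) > 0))
    stop("no bin gene present in the matrix", call. = FALSE)
  keep <- lengths(gene_ok) > 0
  bins <- bins[keep, , drop = FALSE]
  gene_ok <- gene_ok[keep]

  # bin means via one sparse multiply: cells x genes . genes x bins
  memb <- rep(seq_along(gene_ok), lengths(gene_ok))
  gidx <- match(unlist(gene_ok), colnames(norm))
  W <- Matrix::sparseMatrix(i = gidx, j = memb,
                            x = 1 / lengths(gene_ok)[memb],
                            dims = c(ncol(norm), nrow(bins)))
  B <- as.matrix(norm %*% W)
  dimnames(B) <- list(rownames(norm), bins$bin)

  # smooth before centering: smoothed bin values are near-continuous, so the
  # per-bin median across cells is a robust diploid baseline even when a
  # minority of cells carry the event
  B <- smooth_bins(B, bins, smooth_span)

  if (identical(reference, "median")) {
    # blind baseline: per-bin median across all cells resists a minority of
    # event-carrying cells
    center <- apply(B, 2, stats::median)
    ref_desc <- "median of all cells"
  } else {
    # a user-supplied known-diploid reference is trusted: use the unbiased
    # per-bin mean
    if (is.character(reference)) reference <- rownames(B) %in% reference
    ref_rows <- which(reference)
    if (!length(ref_rows)) stop("reference mask is empty", call. = FALSE)
    center <- colMeans(B[ref_rows, , drop = FALSE])
    ref_desc <- sprintf("mean of %d reference cells", length(ref_rows))
  }
  B <- sweep(B, 2, center)
  # per-cell genome-wide recentering: removes cell-level offsets (depth,
  # detection-rate skew) so diploid chromosomes sit at ~0; whole-chromosome
  # events cover a small genome fraction and survive the median
  B <- sweep(B, 1, apply(B, 1, stats::median))
  structure(list(log_ratio = B, bins = bins, reference_description = ref_desc),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("<cnv_profile> ", nrow(x$log_ratio), " cells x ", ncol(x$log_ratio),
      " bins (", length(unique(x$bins$chromosome)), " chromosomes), ",
      x$reference_description, "\n", sep = "")
  invisible(x)
}

#' Call whole-chromosome gains and losses per cell
#'
#' A chromosome is called `gain` for a cell when at least `min_bin_fraction`
#' of its bins exceed `gain_min`; `loss` symmetrically below `loss_max`;
#' otherwise `neutral`. If both fractions qualify the larger wins.
#'
#' @param profile A `cnv_profile` from [infer_cnv()].
#' @param gain_min Log-ratio above which a bin supports a gain
#'   (default +0.15).
#' @param loss_max Log-ratio below which a bin supports a loss
#'   (default -0.15).
#' @param min_bin_fraction Fraction of a chromosome's bins that must agree
#'   (default 0.5).
#' @return Character matrix cells x chromosomes with entries
#'   `"gain"`/`"neutral"`/`"loss"`.
#' @export
call_chromosome_events <- function(profile, gain_min = 0.15,
                                   loss_max = -0.15,
                                   min_bin_fraction = 0.5) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (gain_min <= 0 || loss_max >= 0)
    stop("gain_min must be positive and loss_max negative", call. = FALSE)
  chroms <- unique(profile$bins$chromosome)
  single <- chroms[table(profile$bins$chromosome)[chroms] == 1L]
  if (length(single))
    warning("chromosome(s) with a single bin, call made on that bin: ",
            paste(single, collapse = ", "), call. = FALSE)
  calls <- matrix("neutral", nrow(profile$log_ratio), length(chroms),
                  dimnames = list(rownames(profile$log_ratio), chroms))
  for (chr in chroms) {
    j <- profile$bins$chromosome == chr
    lr <- profile$log_ratio[, j, drop = FALSE]
    fg <- rowMeans(lr > gain_min)
    fl <- rowMeans(lr < loss_max)
    calls[fg >= min_bin_fraction & fg >= fl, chr] <- "gain"
    calls[fl >= min_bin_fraction & fl > fg, chr] <- "loss"
  }
  calls
}

#' Flag cells with the glioblastoma hallmark genotype
#'
#' TRUE for cells called both chromosome 7 gain and chromosome 10 loss — the
#' canonical chr7+/chr10- copy-number genotype of glioblastoma malignant
#' cells.
#'
#' @param calls Character matrix from [call_chromosome_events()].
#' @return Named logical vector per cell.
#' @export
is_gbm_malignant <- function(calls) {
  if (!all(c("7", "10") %in% colnames(calls)))
    stop("calls must cover chromosomes 7 and 10; the chr7+/chr10- genotype ",
         "is undefined without them", call. = FALSE)
  out <- calls[, "7"] == "gain" & calls[, "10"] == "loss"
  stats::setNames(out, rownames(calls))
}
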