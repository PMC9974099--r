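#' Gaussian kernel on normalized expression
#'
#' `k(u) = exp(-u^2 / (2 h^2))`: equals 1 at `u = 0` and decays strictly with
#' `|u|`, so it measures closeness of a gene's normalized expression to zero.
#' [panel_probability()] credits positive markers by `1 - k(u)` (degree of
#' expression) and negative markers by `k(u)` (degree of absence).
#'
#' @param u Numeric vector/matrix of normalized expression values.
#' @param h Bandwidth (> 0), on the natural-log normalized expression scale.
#' @return Values in (0, 1], same shape as `u`.
#' @examples
#' gaussian_kernel(0, 1)        # 1
#' gaussian_kernel(1, 1)        # exp(-1/2)
#' @export
gaussian_kernel <- function(u, h = 1.0) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("bandwidth h must be a single positive number", call. = FALSE)
  exp(-u^2 / (2 * h^2))
}

#' Kernel-based marker-panel probability score
#'
#' For each cell, with `k` the Gaussian kernel of bandwidth `h` applied to
#' log-normalized expression `u`:
#'
#' `p = clamp_01( (1/n) * [ sum_pos (1 - k(u_g)) + sum_neg k(u_g) ] )`
#'
#' so a cell scores high when it expresses the positive markers and lacks the
#' negative markers; `n` is the number of panel genes found in the matrix.
#' Panel genes absent from the matrix are dropped from the sum and from `n`
#' and reported in `missing_genes`.
#'
#' @param norm Log-normalized cells x genes matrix from [log_normalize()].
#' @param panel A [marker_panel()].
#' @param h Kernel bandwidth (default 1.0).
#' @return A `score_result`: list with `scores` (`data.frame`: cell, p),
#'   `n` (panel genes used), `h`, `missing_genes`, `panel_name`.
#' @export
panel_probability <- function(norm, panel, h = 1.0) {
  stopifnot(inherits(panel, "marker_panel"))
  pos <- intersect(panel$positives, colnames(norm))
  neg <- intersect(panel$negatives, colnames(norm))
  missing <- setdiff(c(panel$positives, panel$negatives), colnames(norm))
  n <- length(pos) + length(neg)
  if (n == 0L)
    stop("no gene of panel '", panel$name, "' is present in the matrix",
         call. = FALSE)
  acc <- rep(0, nrow(norm))
  if (length(pos)) {
    kp <- gaussian_kernel(as.matrix(norm[, pos, drop = FALSE]), h)
    acc <- acc + rowSums(1 - kp)
  }
  if (length(neg)) {
    kn <- gaussian_kernel(as.matrix(norm[, neg, drop = FALSE]), h)
    acc <- acc + rowSums(kn)
  }
  p <- pmin(pmax(acc / n, 0), 1)
  structure(list(scores = data.frame(cell = rownames(norm), p = unname(p),
                                     stringsAsFactors = FALSE),
                 n = n, h = h, missing_genes = missing,
                 panel_name = panel$name),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("<score_result> panel '", x$panel_name, "': ", nrow(x$scores),
      " cells, n = ", x$n, " genes, h = ", format(x$h), "\n", sep = "")
  print(summary(x$scores$p))
  if (length(x$missing_genes))
    cat("  missing from matrix:", paste(x$missing_genes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Astrocyte probability score
#'
#' [panel_probability()] with an all-positive panel (default: the 10-gene
#' astrocyte panel of [gbm_marker_panels()]); with no negative markers the
#' score reduces to the mean expressed-ness of the panel genes.
#'
#' @inheritParams panel_probability
#' @param astro_panel All-positive [marker_panel()].
#' @return A `score_result`.
#' @export
astrocyte_probability <- function(norm,
                                  astro_panel = gbm_marker_panels()$astrocyte,
                                  h = 1.0) {
  panel_probability(norm, astro_panel, h)
}

#' Negative selection on exclusion markers
#'
#' Excludes every cell in which any exclusion gene is detected (raw count
#' >= `detect_min`), the detection-based reading of sorting out epithelial
#' (EPCAM), endothelial (PECAM1), pericyte (CSPG4) and immune (PTPRC) cells.
#'
#' @param m Cells x genes count matrix.
#' @param exclusion_genes Genes whose detection excludes a cell.
#' @param detect_min Minimal count that counts as detection (default 1).
#' @return Logical vector (TRUE = retained), named by cell. Attribute
#'   `"exclusion_tally"` counts excluded cells per gene.
#' @export
negative_selection <- function(m,
                               exclusion_genes = c("EPCAM", "PECAM1",
                                                   "CSPG4", "PTPRC"),
                               detect_min = 1L) {
  validate_count_matrix(m)
  present <- intersect(exclusion_genes, colnames(m))
  absent <- setdiff(exclusion_genes, colnames(m))
  if (length(absent))
    warning("exclusion gene(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  excluded <- rep(FALSE, nrow(m))
  tally <- stats::setNames(integer(length(present)), present)
  for (g in present) {
    hit <- m[, g] >= detect_min
    tally[g] <- sum(hit)
    excluded <- excluded | hit
  }
  retained <- stats::setNames(!excluded, rownames(m))
  attr(retained, "exclusion_tally") <- tally
  retained
}

#' Fraction of cells detecting a gene
#'
#' @param m Cells x genes count matrix.
#' @param gene Gene id (must be present).
#' @param detect_min Minimal count that counts as detection (default 1).
#' @param within Optional logical cell mask restricting the denominator.
#' @return Fraction of (masked) cells with count >= `detect_min`.
#' @export
marker_prevalence <- function(m, gene, detect_min = 1L, within = NULL) {
  validate_count_matrix(m)
  if (!gene %in% colnames(m))
    stop("gene not present in matrix: ", gene, call. = FALSE)
  v <- m[, gene]
  if (!is.null(within)) v <- v[within]
  if (!length(v)) return(NA_real_)
  mean(v >= detect_min)
}

#' Fraction of cells detecting at least one panel gene
#'
#' @param m Cells x genes count matrix.
#' @param panel_positives Character vector of panel genes.
#' @param detect_min Minimal count that counts as detection (default 1).
#' @param within Optional logical cell mask.
#' @return Fraction of (masked) cells with >= 1 panel gene detected.
#' @export
panel_coverage <- function(m, panel_positives, detect_min = 1L,
                           within = NULL) {
  validate_count_matrix(m)
  present <- intersect(panel_positives, colnames(m))
  if (!length(present))
    stop("no panel gene present in the matrix", call. = FALSE)
  if (length(present) < length(panel_positives))
    warning("panel gene(s) absent from matrix, skipped: ",
            paste(setdiff(panel_positives, present), collapse = ", "),
            call. = FALSE)
  any_hit <- Matrix::rowSums(m[, present, drop = FALSE] >= detect_min) > 0
  if (!is.null(within)) any_hit <- any_hit[within]
  if (!length(any_hit)) return(NA_real_)
  mean(any_hit)
}

#' Cutoff for calling a score "high"
#'
#' @param scores A `score_result` from [panel_probability()].
#' @param method `"fixed"` (cutoff = `value`) or `"quantile"` (cutoff = the
#'   `value`-quantile of the scores).
#' @param value Cutoff (fixed) or quantile level in (0, 1).
#' @return List with `cutoff` and `mask` (logical, TRUE = flagged; ties at
#'   the cutoff are flagged).
#' @export
high_score_cutoff <- function(scores, method = c("fixed", "quantile"),
                              value = 0.6) {
  stopifnot(inherits(scores, "score_result"))
  method <- match.arg(method)
  p <- scores$scores$p
  if (!length(p)) stop("empty score set", call. = FALSE)
  if (method == "quantile") {
    if (value <= 0 || value >= 1)
      stop("quantile value must be in (0, 1)", call. = FALSE)
    cutoff <- unname(stats::quantile(p, value))
  } else {
    cutoff <- value
  }
  mask <- stats::setNames(p >= cutoff, scores$scores$cell)
  list(cutoff = cutoff, mask = mask)
}
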