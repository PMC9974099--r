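#' Area under the ROC curve of a score against binary truth
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param score Numeric scores.
#' @param truth Logical (or 0/1) vector; TRUE = positive class.
#' @return AUC in [0, 1].
#' @export
score_auc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# classification metrics of a flag against binary truth
flag_metrics <- function(flag, truth) {
  flag <- as.logical(flag); truth <- as.logical(truth)
  c(sensitivity = if (any(truth)) mean(flag[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!flag[!truth]) else NA_real_,
    precision = if (any(flag)) mean(truth[flag]) else NA_real_,
    recall = if (any(truth)) mean(flag[truth]) else NA_real_)
}
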