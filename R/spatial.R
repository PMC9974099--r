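#' Read a spatial spot table
#'
#' @param path TSV with columns `spot`, `x`, `y` and one probability column
#'   per cell type (values in [0, 1]).
#' @return A `spatial_map` data.frame.
#' @export
read_spatial_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("spot", "x", "y")
  if (!all(need %in% names(tab)))
    stop("spot TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  types <- setdiff(names(tab), need)
  if (!length(types)) stop("no cell-type columns in spot table",
                           call. = FALSE)
  for (ct in types) {
    if (any(tab[[ct]] < 0 | tab[[ct]] > 1))
      stop("probabilities for '", ct, "' outside [0, 1]", call. = FALSE)
  }
  class(tab) <- c("spatial_map", "data.frame")
  attr(tab, "celltypes") <- types
  tab
}

map_celltypes <- function(map) {
  ct <- attr(map, "celltypes")
  if (is.null(ct)) ct <- setdiff(names(map), c("spot", "x", "y"))
  ct
}

#' Select high-probability source spots
#'
#' Returns the spots whose probability for `source_type` falls in the top
#' `top_quantile` of the map (ties at the cutoff included), i.e. the
#' ranked-probability definition of "source" spots for proximity analysis.
#'
#' @param map A `spatial_map`.
#' @param source_type Cell-type column to rank.
#' @param top_quantile Fraction of spots to keep (default 0.1).
#' @return Integer vector of spot row indices.
#' @export
rank_source_spots <- function(map, source_type, top_quantile = 0.1) {
  if (top_quantile <= 0 || top_quantile >= 1)
    stop("top_quantile must be in (0, 1)", call. = FALSE)
  if (!source_type %in% map_celltypes(map))
    stop("unknown cell type: ", source_type, call. = FALSE)
  p <- map[[source_type]]
  k <- ceiling(top_quantile * length(p))
  cut <- sort(p, decreasing = TRUE)[k]
  which(p >= cut)
}

#' Proximity curve of a target cell type around source spots
#'
#' Computes every spot's Euclidean distance to its nearest source spot, bins
#' the distances into `n_bins` equal-width bins over [0, max distance], and
#' reports the mean target probability per bin. Source spots themselves fall
#' in bin 0. Empty bins are reported with `n_spots = 0` and `NA` mean, never
#' interpolated.
#'
#' @param map A `spatial_map`.
#' @param source_spots Row indices from [rank_source_spots()].
#' @param target_type Cell-type column to average.
#' @param n_bins Number of distance bins (default 20).
#' @return `data.frame` with columns `bin_mid`, `mean_prob`, `n_spots`.
#' @export
proximity_curve <- function(map, source_spots, target_type, n_bins = 20) {
  if (!length(source_spots)) stop("source_spots is empty", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (!target_type %in% map_celltypes(map))
    stop("unknown cell type: ", target_type, call. = FALSE)
  dx <- outer(map$x, map$x[source_spots], "-")
  dy <- outer(map$y, map$y[source_spots], "-")
  d <- sqrt(dx^2 + dy^2)
  dmin <- apply(d, 1, min)
  dmax <- max(dmin)
  if (dmax == 0) {
    warning("degenerate map: all spots coincide with a source",
            call. = FALSE)
    return(data.frame(bin_mid = 0, mean_prob = mean(map[[target_type]]),
                      n_spots = nrow(map)))
  }
  breaks <- seq(0, dmax, length.out = n_bins + 1)
  idx <- pmin(findInterval(dmin, breaks, rightmost.closed = TRUE), n_bins)
  p <- map[[target_type]]
  n_spots <- tabulate(idx, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(p[idx == b]), 0)
  data.frame(bin_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
             mean_prob = ifelse(n_spots > 0, sums / n_spots, NA_real_),
             n_spots = n_spots)
}

#' Pearson correlation between two probability fields
#'
#' @param map A `spatial_map` with at least 3 spots.
#' @param typeA,typeB Cell-type columns.
#' @return List with `pearson_r` and `r_squared`.
#' @export
spatial_correlation <- function(map, typeA, typeB) {
  for (ct in c(typeA, typeB)) {
    if (!ct %in% map_celltypes(map))
      stop("unknown cell type: ", ct, call. = FALSE)
  }
  if (nrow(map) < 3) stop("need at least 3 spots", call. = FALSE)
  a <- map[[typeA]]; b <- map[[typeB]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant probability field: correlation undefined", call. = FALSE)
  r <- stats::cor(a, b)
  list(pearson_r = r, r_squared = r^2)
}

#' Write a spatial spot table
#'
#' @param map A `spatial_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spatial_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
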