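#' Simulation configuration
#'
#' Bundles every parameter of the synthetic scRNA-seq generator. Counts are
#' negative-binomial with cell-specific depth; each population exclusively
#' expresses its catalog marker genes at `marker_fold_change` times the
#' baseline per-gene weight; malignant cells additionally carry a chromosome 7
#' gain and chromosome 10 loss as multiplicative shifts of gene means — the
#' glioblastoma hallmark genotype the CNV caller looks for.
#'
#' Per-gene means are relative weights normalized within each cell, so a
#' cell's expected total equals its drawn depth and its expected mitochondrial
#' fraction equals its drawn Beta value.
#'
#' @param n_cells Number of cells.
#' @param population_fractions Named numeric vector of population fractions;
#'   must be nonnegative and sum to 1. Default mirrors the composition of
#'   serially trypsinized glioblastoma cells: 52% CAF, 22% myeloid,
#'   20% malignant, 6% oligodendrocyte.
#' @param n_genes Number of nuclear genes in the universe (13 `MT-` genes are
#'   appended on top).
#' @param marker_assignments Named list mapping population label to the genes
#'   it exclusively expresses; see [default_marker_assignments()]. Every
#'   catalog gene is silent outside its own population.
#' @param marker_fold_change Fold elevation of a population's own markers
#'   over the baseline gene weight (default 8).
#' @param baseline_mean Baseline relative weight of a non-marker gene
#'   (default 0.2; only the ratio to `marker_fold_change` matters after
#'   within-cell normalization).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.5).
#' @param depth_lognormal_mu_sigma Log-normal parameters of per-cell depth,
#'   default `c(log(5000), 0.35)`.
#' @param mito_fraction_beta_params Beta parameters of the per-cell
#'   mitochondrial fraction, default `c(2, 38)` (mean 5%).
#' @param cnv_gain_fold Multiplicative shift of chromosome 7 gene means in
#'   malignant cells (default 1.5).
#' @param cnv_loss_fold Multiplicative shift of chromosome 10 gene means in
#'   malignant cells (default 0.5, must be in (0,1)).
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output bit for bit.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_cells = 5000,
                              population_fractions = c(CAF = 0.52,
                                                       myeloid = 0.22,
                                                       malignant = 0.20,
                                                       oligodendrocyte = 0.06),
                              n_genes = 2000,
                              marker_assignments = default_marker_assignments(),
                              marker_fold_change = 8,
                              baseline_mean = 0.2,
                              nb_dispersion = 0.5,
                              depth_lognormal_mu_sigma = c(log(5000), 0.35),
                              mito_fraction_beta_params = c(2, 38),
                              cnv_gain_fold = 1.5,
                              cnv_loss_fold = 0.5,
                              seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              population_fractions = population_fractions,
              n_genes = as.integer(n_genes),
              marker_assignments = marker_assignments,
              marker_fold_change = marker_fold_change,
              baseline_mean = baseline_mean,
              nb_dispersion = nb_dispersion,
              depth_lognormal_mu_sigma = depth_lognormal_mu_sigma,
              mito_fraction_beta_params = mito_fraction_beta_params,
              cnv_gain_fold = cnv_gain_fold,
              cnv_loss_fold = cnv_loss_fold,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- cfg$population_fractions
  if (is.null(names(fr)) || any(!nzchar(names(fr))))
    stop("population_fractions must be a named vector", call. = FALSE)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("population fractions must be nonnegative and sum to 1",
         call. = FALSE)
  if (cfg$n_cells < 1L) stop("n_cells must be positive", call. = FALSE)
  pos <- c(marker_fold_change = cfg$marker_fold_change,
           baseline_mean = cfg$baseline_mean,
           nb_dispersion = cfg$nb_dispersion,
           cnv_gain_fold = cfg$cnv_gain_fold,
           cnv_loss_fold = cfg$cnv_loss_fold,
           depth_sigma = cfg$depth_lognormal_mu_sigma[2],
           mito_a = cfg$mito_fraction_beta_params[1],
           mito_b = cfg$mito_fraction_beta_params[2])
  if (any(pos <= 0))
    stop("scale parameters must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  if (cfg$cnv_loss_fold >= 1)
    stop("cnv_loss_fold must be in (0, 1)", call. = FALSE)
  mk <- unlist(cfg$marker_assignments, use.names = FALSE)
  if (anyDuplicated(mk))
    stop("a marker gene may appear in exactly one population's list: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cells, " cells, ", x$n_genes, " genes + 13 MT\n",
      sep = "")
  fr <- x$population_fractions
  cat("  populations:",
      paste(sprintf("%s=%.2f", names(fr), fr), collapse = ", "), "\n")
  cat(sprintf("  marker fold %.3g, NB dispersion %.3g, CNV folds %.3g/%.3g, seed %d\n",
              x$marker_fold_change, x$nb_dispersion, x$cnv_gain_fold,
              x$cnv_loss_fold, x$seed))
  invisible(x)
}

#' Simulate a labeled single-cell count matrix
#'
#' Draws population labels by multinomial sampling at the configured
#' fractions, per-cell depths (log-normal) and mitochondrial fractions
#' (Beta), then negative-binomial counts gene by gene. A population's own
#' catalog markers get `marker_fold_change` times the baseline weight and are
#' silent in every other population; malignant cells carry the chr7-gain /
#' chr10-loss multiplicative shifts. Mitochondrial genes share the drawn mito
#' fraction of each cell's depth equally.
#'
#' @param config A [simulation_config()].
#' @return An object of class `sim_counts`: list with `counts` (sparse
#'   cells x genes `dgCMatrix`), `truth_labels` (named character vector),
#'   `gene_annotation` (`data.frame`: gene, chromosome, start) and `config`.
#' @examples
#' sim <- simulate_counts(simulation_config(n_cells = 50, n_genes = 300))
#' table(sim$truth_labels)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  ann <- gene_universe(config$n_genes)
  genes <- ann$gene
  is_mito <- ann$chromosome == "MT"
  catalog <- unlist(config$marker_assignments, use.names = FALSE)
  missing_mk <- setdiff(intersect(catalog, catalog), genes)
  if (length(missing_mk))
    stop("marker gene(s) not in gene universe: ",
         paste(missing_mk, collapse = ", "), call. = FALSE)

  pops <- names(config$population_fractions)
  pop_counts <- stats::rmultinom(1, config$n_cells,
                                 config$population_fractions)[, 1]
  labels <- sample(rep(pops, pop_counts))
  depth <- stats::rlnorm(config$n_cells,
                         config$depth_lognormal_mu_sigma[1],
                         config$depth_lognormal_mu_sigma[2])
  mito_f <- stats::rbeta(config$n_cells,
                         config$mito_fraction_beta_params[1],
                         config$mito_fraction_beta_params[2])

  # population-level relative weights over nuclear genes
  base_w <- rep(config$baseline_mean, sum(!is_mito))
  names(base_w) <- genes[!is_mito]
  base_w[intersect(catalog, names(base_w))] <- 0
  nuc_chrom <- ann$chromosome[!is_mito]
  size <- 1 / config$nb_dispersion

  counts <- matrix(0L, nrow = config$n_cells, ncol = length(genes),
                   dimnames = list(sprintf("cell%05d", seq_len(config$n_cells)),
                                   genes))
  for (pop in pops) {
    idx <- which(labels == pop)
    if (!length(idx)) next
    w <- base_w
    own <- intersect(config$marker_assignments[[pop]], names(w))
    w[own] <- config$baseline_mean * config$marker_fold_change
    if (pop == "malignant") {
      w[nuc_chrom == "7"] <- w[nuc_chrom == "7"] * config$cnv_gain_fold
      w[nuc_chrom == "10"] <- w[nuc_chrom == "10"] * config$cnv_loss_fold
    }
    w <- w / sum(w)
    mu <- cbind(outer(depth[idx] * (1 - mito_f[idx]), w),
                outer(depth[idx] * mito_f[idx], rep(1 / 13, 13)))
    draw <- stats::rnbinom(length(mu), size = size, mu = as.vector(mu))
    counts[idx, ] <- matrix(draw, nrow = length(idx))
  }
  names(labels) <- rownames(counts)
  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 truth_labels = labels,
                 gene_annotation = ann,
                 config = config),
            class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cat("<sim_counts> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  print(table(x$truth_labels))
  invisible(x)
}

#' Simulate paired bulk expression profiles with planted crosstalk
#'
#' Builds two bulk profiles (labels `A` and `B`), each carrying an FPKM layer
#' (ligand side) and a read-count layer (receptor side), such that exactly
#' `n_ab` database pairs pass the crosstalk thresholds in the A -> B direction
#' and exactly `n_ba` in the B -> A direction. The remaining pairs are failed
#' deliberately: some by a sub-threshold ligand, some by a sub-threshold
#' receptor, and some placed exactly at a threshold (strict inequalities must
#' exclude them).
#'
#' @param db An [lr_database()] with at least `n_ab + n_ba + 2` pairs.
#' @param n_ab,n_ba Number of pairs planted above threshold in each direction.
#' @param fpkm_min,counts_min The thresholds the plants straddle
#'   (defaults 0.05 FPKM, 10 counts).
#' @param seed Integer seed.
#' @return List with `A` and `B` (each `list(fpkm=, counts=)` named numeric
#'   vectors over genes), and `truth`: `data.frame` of pair, direction and
#'   planted status (`"pass"`, `"ligand_fail"`, `"receptor_fail"`,
#'   `"at_threshold"`).
#' @export
simulate_bulk_profiles <- function(db, n_ab = 10, n_ba = 7,
                                   fpkm_min = 0.05, counts_min = 10,
                                   seed = 1L) {
  stopifnot(inherits(db, "lr_database"))
  npair <- nrow(db$pairs)
  if (npair < n_ab + n_ba + 2)
    stop("database too small for the requested plants", call. = FALSE)
  if (anyDuplicated(c(db$pairs$ligand, db$pairs$receptor)))
    stop("planting exact edge counts requires pairs with distinct genes",
         call. = FALSE)
  set.seed(as.integer(seed))
  status <- rep("ligand_fail", npair)
  direction <- rep(NA_character_, npair)
  ord <- sample.int(npair)
  take <- function(k) { out <- ord[seq_len(k)]; ord <<- ord[-seq_len(k)]; out }
  i_ab <- take(n_ab); i_ba <- take(n_ba)
  i_at <- take(min(2L, length(ord)))
  i_rf <- if (length(ord)) ord[seq_len(ceiling(length(ord) / 2))] else integer()
  status[i_ab] <- "pass"; direction[i_ab] <- "A->B"
  status[i_ba] <- "pass"; direction[i_ba] <- "B->A"
  status[i_at] <- "at_threshold"
  status[i_rf] <- "receptor_fail"

  genes <- unique(c(db$pairs$ligand, db$pairs$receptor))
  lo_f <- fpkm_min / 5; lo_c <- floor(counts_min / 2)
  blank <- function() stats::setNames(rep(0, length(genes)), genes)
  A <- list(fpkm = blank(), counts = blank())
  B <- list(fpkm = blank(), counts = blank())
  bump_f <- function() fpkm_min * stats::runif(1, 2, 50)
  bump_c <- function() counts_min + sample(5:500, 1)
  for (i in seq_len(npair)) {
    lg <- db$pairs$ligand[i]; rc <- db$pairs$receptor[i]
    if (status[i] == "pass" && direction[i] == "A->B") {
      A$fpkm[lg] <- bump_f()
      B$counts[rc] <- bump_c()
    } else if (status[i] == "pass" && direction[i] == "B->A") {
      B$fpkm[lg] <- bump_f()
      A$counts[rc] <- bump_c()
    } else if (status[i] == "at_threshold") {
      # exactly at both thresholds in both directions: strict rules drop it
      A$fpkm[lg] <- fpkm_min; B$fpkm[lg] <- fpkm_min
      A$counts[rc] <- counts_min; B$counts[rc] <- counts_min
    } else if (status[i] == "receptor_fail") {
      # ligand expressed on both sides, receptor below threshold everywhere
      A$fpkm[lg] <- bump_f(); B$fpkm[lg] <- bump_f()
      A$counts[rc] <- lo_c; B$counts[rc] <- lo_c
    } else { # ligand_fail: ligand below threshold, receptor expressed
      A$fpkm[lg] <- lo_f; B$fpkm[lg] <- lo_f
      A$counts[rc] <- bump_c(); B$counts[rc] <- bump_c()
    }
  }
  truth <- data.frame(ligand = db$pairs$ligand, receptor = db$pairs$receptor,
                      status = status, direction = direction,
                      stringsAsFactors = FALSE)
  list(A = A, B = B, truth = truth)
}

#' Simulate a spatial cell-type probability map
#'
#' Lays a regular `n_spots_side` x `n_spots_side` grid on the unit square and
#' gives each cell type a probability field built from a mixture of planar
#' Gaussian bumps, rescaled to [0, 1]. Cell types listed together in
#' `colocalized_pairs` share bump centers (with independent amplitudes and a
#' little field noise); all other types draw independent centers.
#'
#' @param n_spots_side Grid side length (>= 4).
#' @param celltypes Character vector of cell-type labels.
#' @param colocalized_pairs List of length-2 character vectors naming pairs
#'   that should share spatial structure.
#' @param n_bumps Number of Gaussian bumps per field (default 3).
#' @param bump_sd Bump width as a fraction of the unit square (default 0.12).
#' @param noise_sd Additive Gaussian field noise before rescaling
#'   (default 0.02).
#' @param seed Integer seed.
#' @return A `spatial_map`: `data.frame` with columns `spot`, `x`, `y` and one
#'   probability column per cell type. Attribute `"bump_centers"` records the
#'   planted bump centers per cell type (ground truth for proximity tests).
#' @export
simulate_spatial_map <- function(n_spots_side, celltypes,
                                 colocalized_pairs = list(),
                                 n_bumps = 3, bump_sd = 0.12,
                                 noise_sd = 0.02, seed = 1L) {
  if (n_spots_side < 4) stop("n_spots_side must be >= 4", call. = FALSE)
  for (p in colocalized_pairs) {
    if (!all(p %in% celltypes))
      stop("unknown cell type in colocalized_pairs: ",
           paste(setdiff(p, celltypes), collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  g <- seq(0, 1, length.out = n_spots_side)
  grid <- expand.grid(x = g, y = g, KEEP.OUT.ATTRS = FALSE)

  # union-find over colocalization pairs -> shared center groups
  group <- stats::setNames(seq_along(celltypes), celltypes)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (p in colocalized_pairs) {
    a <- find(match(p[1], celltypes)); b <- find(match(p[2], celltypes))
    group[a] <- b
  }
  roots <- vapply(seq_along(celltypes), find, integer(1))
  centers <- list()
  out <- data.frame(spot = sprintf("spot%04d", seq_len(nrow(grid))),
                    x = grid$x, y = grid$y, stringsAsFactors = FALSE)
  for (i in seq_along(celltypes)) {
    r <- as.character(roots[i])
    if (is.null(centers[[r]]))
      centers[[r]] <- cbind(stats::runif(n_bumps), stats::runif(n_bumps))
    cen <- centers[[r]]
    amp <- stats::runif(n_bumps, 0.5, 1)
    f <- rep(0, nrow(grid))
    for (b in seq_len(n_bumps)) {
      d2 <- (grid$x - cen[b, 1])^2 + (grid$y - cen[b, 2])^2
      f <- f + amp[b] * exp(-d2 / (2 * bump_sd^2))
    }
    f <- f + stats::rnorm(nrow(grid), 0, noise_sd)
    f <- pmin(pmax((f - min(f)) / (max(f) - min(f)), 0), 1)
    out[[celltypes[i]]] <- f
  }
  class(out) <- c("spatial_map", "data.frame")
  attr(out, "celltypes") <- celltypes
  attr(out, "bump_centers") <-
    stats::setNames(lapply(as.character(roots), function(r) centers[[r]]),
                    celltypes)
  out
}
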