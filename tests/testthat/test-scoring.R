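# independent transcription of the score: direct per-cell loop over the
# formula p = clamp01( (1/n) [ sum_pos (1 - k(u)) + sum_neg k(u) ] )
oracle_panel_p <- function(u_pos, u_neg, h) {
  k <- function(u) exp(-u^2 / (2 * h^2))
  n <- length(u_pos) + length(u_neg)
  p <- (sum(1 - k(u_pos)) + sum(k(u_neg))) / n
  min(max(p, 0), 1)
}

test_that("the Gaussian kernel matches its closed forms", {
  expect_equal(gaussian_kernel(0, 1), 1, tolerance = 1e-12)
  expect_equal(gaussian_kernel(2, 2), exp(-1 / 2), tolerance = 1e-12)
  expect_equal(gaussian_kernel(4, 1), exp(-8), tolerance = 1e-12)
  u <- seq(0, 5, by = 0.25)
  expect_true(all(diff(gaussian_kernel(u, 1.3)) < 0))
  expect_error(gaussian_kernel(1, 0), "positive")
  expect_error(gaussian_kernel(1, -2), "positive")
})

test_that("panel probability equals the independent transcription on small panels", {
  set.seed(99)
  for (rep in 1:20) {
    n_pos <- sample(1:2, 1)
    n_neg <- sample(0:1, 1)
    h <- runif(1, 0.3, 3)
    genes <- paste0("g", seq_len(n_pos + n_neg))
    panel <- marker_panel("t", positives = genes[seq_len(n_pos)],
                          negatives = if (n_neg) genes[n_pos + 1] else
                            character())
    u <- matrix(runif(3 * length(genes), 0, 6), nrow = 3,
                dimnames = list(paste0("c", 1:3), genes))
    norm <- Matrix::Matrix(u, sparse = TRUE)
    got <- panel_probability(norm, panel, h)$scores$p
    want <- apply(u, 1, function(row) {
      oracle_panel_p(row[panel$positives],
                     row[panel$negatives], h)
    })
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("degenerate expression patterns hit the score's limits", {
  panel <- gbm_marker_panels()$caf
  genes <- c(panel$positives, panel$negatives)
  zero <- tiny_counts(rep(0, 14), cells = "c1", genes = genes)
  expect_equal(panel_probability(zero, panel)$scores$p, 5 / 14,
               tolerance = 1e-12)
  sat_pos <- tiny_counts(c(rep(50, 9), rep(0, 5)), cells = "c1",
                         genes = genes)
  expect_equal(panel_probability(sat_pos, panel)$scores$p, 1,
               tolerance = 1e-6)
  sat_neg <- tiny_counts(c(rep(0, 9), rep(50, 5)), cells = "c1",
                         genes = genes)
  expect_equal(panel_probability(sat_neg, panel)$scores$p, 0,
               tolerance = 1e-6)
})

test_that("missing panel genes are dropped from n and reported", {
  panel <- gbm_marker_panels()$caf
  m <- tiny_counts(c(3, 0), cells = "c1", genes = c("ACTA2", "PTPRC"))
  res <- panel_probability(m, panel)
  expect_identical(res$n, 2L)
  expect_setequal(res$missing_genes,
                  setdiff(c(panel$positives, panel$negatives),
                          c("ACTA2", "PTPRC")))
  none <- tiny_counts(c(1), cells = "c1", genes = "OTHER")
  expect_error(panel_probability(none, panel), "panel")
})

test_that("score is invariant to gene permutation and off-panel genes", {
  set.seed(4)
  genes <- c("ACTA2", "FAP", "PTPRC", "JUNK1", "JUNK2")
  u <- matrix(runif(10, 0, 4), nrow = 2,
              dimnames = list(c("c1", "c2"), genes))
  panel <- marker_panel("t", positives = c("ACTA2", "FAP"),
                        negatives = "PTPRC")
  norm <- Matrix::Matrix(u, sparse = TRUE)
  p1 <- panel_probability(norm, panel)$scores$p
  p2 <- panel_probability(norm[, rev(genes)], panel)$scores$p
  p3 <- panel_probability(norm[, c("ACTA2", "FAP", "PTPRC")], panel)$scores$p
  u2 <- u
  u2[, "JUNK1"] <- 99
  norm2 <- Matrix::Matrix(u2, sparse = TRUE)
  p4 <- panel_probability(norm2, panel)$scores$p
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
  expect_equal(p1, p4, tolerance = 1e-12)
})

test_that("score is monotone in marker expression", {
  panel <- marker_panel("t", positives = "POS", negatives = "NEG")
  p_at <- function(pos, neg) {
    m <- tiny_counts(c(pos, neg), cells = "c1", genes = c("POS", "NEG"))
    panel_probability(m, panel)$scores$p
  }
  pos_path <- vapply(c(0, 1, 2, 4, 8), p_at, 0, neg = 1)
  expect_true(all(diff(pos_path) >= 0))
  neg_path <- vapply(c(0, 1, 2, 4, 8), function(n) p_at(1, n), 0)
  expect_true(all(diff(neg_path) <= 0))
})

test_that("bandwidth limits behave as the kernel dictates", {
  panel <- gbm_marker_panels()$caf
  genes <- c(panel$positives, panel$negatives)
  set.seed(7)
  m <- tiny_counts(rpois(28, 3), cells = c("c1", "c2"), genes = genes)
  # h -> infinity: every kernel -> 1, so p -> |negatives| / n
  p_inf <- panel_probability(m, panel, h = 1e8)$scores$p
  expect_equal(p_inf, rep(5 / 14, 2), tolerance = 1e-9)
  # h -> 0+: kernel is an indicator of u == 0, p counts the detection pattern
  p_0 <- panel_probability(m, panel, h = 1e-8)$scores$p
  u <- as.matrix(m)
  want <- apply(u, 1, function(row) {
    (sum(row[panel$positives] > 0) + sum(row[panel$negatives] == 0)) / 14
  })
  expect_equal(p_0, unname(want), tolerance = 1e-9)
})

test_that("CAF score separates planted CAFs at study scale", {
  b <- default_sim_bundle()
  auc <- score_auc(b$scores$scores$p, b$truth == "CAF")
  expect_gte(auc, 0.95)
  # cross-check the rank AUC against an established implementation
  roc <- pROC::roc(response = b$truth == "CAF",
                   predictor = b$scores$scores$p, quiet = TRUE,
                   direction = "<")
  expect_equal(auc, as.numeric(pROC::auc(roc)), tolerance = 1e-9)
})

test_that("high CAF and high astrocyte scores do not overlap", {
  sim <- simulate_counts(simulation_config(
    n_cells = 800, n_genes = 1000,
    population_fractions = c(CAF = 0.5, astrocyte = 0.5), seed = 21))
  norm <- log_normalize(sim$counts)
  caf_p <- panel_probability(norm, gbm_marker_panels()$caf)$scores$p
  astro_p <- astrocyte_probability(norm)$scores$p
  top <- function(p) p >= quantile(p, 0.9)
  expect_identical(sum(top(caf_p) & top(astro_p)), 0L)
})

test_that("astrocyte score hits its all-positive limits", {
  panel <- gbm_marker_panels()$astrocyte
  zero <- tiny_counts(rep(0, 10), cells = "c1", genes = panel$positives)
  expect_equal(astrocyte_probability(zero)$scores$p, 0, tolerance = 1e-12)
  high <- tiny_counts(rep(80, 10), cells = "c1", genes = panel$positives)
  expect_equal(astrocyte_probability(high)$scores$p, 1, tolerance = 1e-6)
})

test_that("negative selection excludes on any detected exclusion marker", {
  m <- tiny_counts(c(1, 0, 0, 0, 5,
                     0, 0, 0, 0, 9,
                     0, 2, 1, 0, 0),
                   cells = c("c1", "c2", "c3"),
                   genes = c("EPCAM", "PECAM1", "CSPG4", "PTPRC", "ACTA2"))
  kept <- negative_selection(m)
  expect_identical(as.vector(kept), c(FALSE, TRUE, FALSE))
  tally <- attr(kept, "exclusion_tally")
  expect_identical(tally[["EPCAM"]], 1L)
  expect_identical(tally[["PECAM1"]], 1L)
  m2 <- tiny_counts(c(1, 1), cells = "c1", genes = c("EPCAM", "g1"))
  expect_warning(negative_selection(m2), "PECAM1")
})

test_that("negative selection recovers a planted contaminant fraction", {
  sim <- simulate_counts(simulation_config(
    n_cells = 2000, n_genes = 1000,
    population_fractions = c(CAF = 0.75, myeloid = 0.0625,
                             endothelial = 0.0625, pericyte = 0.0625,
                             epithelial_immune = 0.0625),
    seed = 13))
  kept <- negative_selection(sim$counts)
  expect_within_binom99(mean(kept), length(kept), 0.75)
  # essentially no planted CAF is excluded
  expect_gt(mean(kept[sim$truth_labels == "CAF"]), 0.999)
})

test_that("marker prevalence matches an independent detection-probability oracle", {
  b <- default_sim_bundle()
  cfg <- b$sim$config
  # transcription of the generator's mean model for a CAF cell
  n_catalog <- length(unlist(cfg$marker_assignments, use.names = FALSE))
  S <- cfg$baseline_mean * (cfg$n_genes - n_catalog) +
    cfg$baseline_mean * cfg$marker_fold_change *
      length(cfg$marker_assignments$CAF)
  detect_oracle <- function(w_norm) {
    size <- 1 / cfg$nb_dispersion
    dq <- qlnorm(seq(0.0005, 0.9995, length.out = 400),
                 cfg$depth_lognormal_mu_sigma[1],
                 cfg$depth_lognormal_mu_sigma[2])
    fq <- qbeta(seq(0.005, 0.995, length.out = 100),
                cfg$mito_fraction_beta_params[1],
                cfg$mito_fraction_beta_params[2])
    mu <- outer(dq, 1 - fq) * w_norm
    mean(1 - (size / (size + mu))^size)
  }
  caf <- b$sim$truth_labels == "CAF"
  n_caf <- sum(caf)
  p_marker <- detect_oracle(cfg$baseline_mean * cfg$marker_fold_change / S)
  obs_marker <- marker_prevalence(b$sim$counts, "ACTA2", within = caf)
  expect_within_binom99(obs_marker, n_caf, p_marker)
  # a baseline (non-catalog) gene sits at the baseline detection rate
  p_base <- detect_oracle(cfg$baseline_mean / S)
  obs_base <- marker_prevalence(b$sim$counts, "EVA1B", within = caf)
  expect_within_binom99(obs_base, n_caf, p_base)
})

test_that("prevalence and coverage behave on degenerate input", {
  zeros <- tiny_counts(rep(0, 4), cells = c("c1", "c2"),
                       genes = c("g1", "g2"))
  expect_equal(marker_prevalence(zeros, "g1"), 0)
  expect_equal(panel_coverage(zeros, c("g1", "g2")), 0)
  ones <- tiny_counts(rep(1, 4), cells = c("c1", "c2"),
                      genes = c("g1", "g2"))
  expect_equal(marker_prevalence(ones, "g1"), 1)
  expect_error(marker_prevalence(ones, "nope"), "not present")
  # single-gene coverage reduces to prevalence; coverage dominates any member
  b <- default_sim_bundle()
  m <- b$counts
  expect_equal(panel_coverage(m, "ACTA2"), marker_prevalence(m, "ACTA2"))
  panel <- gbm_marker_panels()$caf$positives
  singles <- vapply(panel, function(g) marker_prevalence(m, g), 0)
  expect_gte(panel_coverage(m, panel), max(singles))
})

test_that("high-score cutoffs flag the intended cells", {
  sr <- structure(list(scores = data.frame(cell = c("a", "b"),
                                           p = c(0.2, 0.7)),
                       n = 14L, h = 1, missing_genes = character(),
                       panel_name = "CAF"),
                  class = "score_result")
  fixed <- high_score_cutoff(sr, "fixed", 0.6)
  expect_identical(sum(fixed$mask), 1L)
  sr$scores <- data.frame(cell = paste0("c", 1:4),
                          p = c(0.1, 0.4, 0.4, 0.9))
  q <- high_score_cutoff(sr, "quantile", 0.5)
  expect_true(all(sr$scores$p[q$mask] >= q$cutoff))
  expect_error(high_score_cutoff(sr, "quantile", 1.5), "in \\(0, 1\\)")
})

test_that("the default cutoff recovers planted CAFs with high precision and recall", {
  b <- default_sim_bundle()
  flagged <- high_score_cutoff(b$scores, "fixed", 0.6)$mask
  fm <- flag_metrics(flagged, b$truth == "CAF")
  expect_gte(fm[["precision"]], 0.90)
  expect_gte(fm[["recall"]], 0.90)
})
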