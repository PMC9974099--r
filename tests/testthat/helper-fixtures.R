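# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

# default study-scale simulation (5,000 cells, fractions .52/.22/.20/.06,
# seed 1) with QC, normalization, CAF scores and clean-reference CNV calls
default_sim_bundle <- function() {
  if (!exists("bundle", envir = .fixture_env)) {
    sim <- simulate_counts(simulation_config(seed = 1))
    qc <- compute_cell_qc(sim$counts)
    mf <- qc_filter(sim$counts, qc)
    norm <- log_normalize(mf)
    truth <- sim$truth_labels[rownames(mf)]
    nuc <- sim$gene_annotation[sim$gene_annotation$chromosome != "MT", ]
    bins <- bin_genes(nuc)
    profile <- infer_cnv(norm, bins,
                         reference = rownames(mf)[truth != "malignant"])
    calls <- call_chromosome_events(profile)
    malignant <- is_gbm_malignant(calls)
    scores <- panel_probability(norm, gbm_marker_panels()$caf)
    assign("bundle",
           list(sim = sim, qc = qc, counts = mf, norm = norm, truth = truth,
                bins = bins, profile = profile, calls = calls,
                malignant = malignant, scores = scores),
           envir = .fixture_env)
  }
  get("bundle", envir = .fixture_env)
}

# small dense count matrix -> dgCMatrix with dimnames
tiny_counts <- function(values, cells, genes) {
  m <- matrix(values, nrow = length(cells), ncol = length(genes),
              byrow = TRUE, dimnames = list(cells, genes))
  Matrix::Matrix(m, sparse = TRUE)
}

# exact two-sided binomial 99% interval for an observed fraction
expect_within_binom99 <- function(observed_fraction, n, p) {
  lo <- stats::qbinom(0.005, n, p) / n
  hi <- stats::qbinom(0.995, n, p) / n
  expect_gte(observed_fraction, lo)
  expect_lte(observed_fraction, hi)
}

lr_fixture_path <- function() {
  system.file("extdata", "lr_pairs_50.tsv", package = "cafid",
              mustWork = TRUE)
}
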