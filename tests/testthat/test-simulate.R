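test_that("configuration validation rejects malformed inputs", {
  expect_error(simulation_config(population_fractions = c(CAF = 0.6,
                                                          myeloid = 0.3)),
               "sum to 1")
  expect_error(simulation_config(population_fractions = c(CAF = 1.2,
                                                          myeloid = -0.2)),
               "nonnegative")
  expect_error(simulation_config(nb_dispersion = 0), "strictly positive")
  expect_error(simulation_config(cnv_loss_fold = 1.2), "in \\(0, 1\\)")
  expect_error(
    simulation_config(marker_assignments = list(CAF = c("ACTA2", "FAP"),
                                                myeloid = c("AIF1", "ACTA2"))),
    "exactly one population")
  expect_error(
    simulate_counts(simulation_config(
      n_cells = 10, n_genes = 200,
      marker_assignments = list(CAF = "NOT_A_GENE"))),
    "not in gene universe")
})

test_that("identical config and seed reproduce counts bit for bit", {
  cfg <- simulation_config(n_cells = 150, n_genes = 300, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth_labels, b$truth_labels)
  expect_identical(a$gene_annotation, b$gene_annotation)
})

test_that("degenerate mixture assigns every cell to the single population", {
  sim <- simulate_counts(simulation_config(
    n_cells = 100, n_genes = 300,
    population_fractions = c(CAF = 1.0), seed = 3))
  expect_setequal(unique(sim$truth_labels), "CAF")
  expect_length(sim$truth_labels, 100)
})

test_that("label fractions at study scale sit in exact binomial 99% intervals", {
  b <- default_sim_bundle()
  labels <- b$sim$truth_labels
  want <- b$sim$config$population_fractions
  for (pop in names(want)) {
    expect_within_binom99(mean(labels == pop), length(labels), want[[pop]])
  }
})

test_that("counts are nonnegative integers and genes annotated exactly once", {
  sim <- simulate_counts(simulation_config(n_cells = 80, n_genes = 250,
                                           seed = 5))
  x <- sim$counts@x
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  expect_false(anyDuplicated(sim$gene_annotation$gene) > 0)
  expect_setequal(colnames(sim$counts), sim$gene_annotation$gene)
  expect_length(sim$truth_labels, nrow(sim$counts))
})

test_that("marker elevation recovers the configured fold change", {
  b <- default_sim_bundle()
  cfg <- b$sim$config
  caf <- b$sim$truth_labels == "CAF"
  m <- b$sim$counts
  catalog <- unlist(cfg$marker_assignments, use.names = FALSE)
  baseline_genes <- setdiff(colnames(m), c(catalog, mito_gene_names()))
  # avoid CNV chromosomes so the comparison isolates the marker fold
  ann <- b$sim$gene_annotation
  baseline_genes <- intersect(baseline_genes,
                              ann$gene[!ann$chromosome %in% c("7", "10")])
  marker_mean <- mean(m[caf, "ACTA2"])
  baseline_mean <- mean(Matrix::rowMeans(m[caf, baseline_genes]))
  ratio <- marker_mean / baseline_mean
  expect_gt(sum(caf), 1000)
  expect_lt(abs(ratio - cfg$marker_fold_change), 0.1 * cfg$marker_fold_change)
})

test_that("marker genes are silent outside their own population", {
  b <- default_sim_bundle()
  myeloid <- b$sim$truth_labels == "myeloid"
  expect_identical(sum(b$sim$counts[!myeloid, "AIF1"]), 0)
  caf <- b$sim$truth_labels == "CAF"
  expect_identical(sum(b$sim$counts[!caf, "COL1A1"]), 0)
})

test_that("mitochondrial fractions track the Beta law", {
  b <- default_sim_bundle()
  qc <- compute_cell_qc(b$sim$counts)
  beta_mean <- 2 / (2 + 38)
  expect_gt(nrow(qc), 2000)
  expect_lt(abs(mean(qc$mito_fraction) - beta_mean), 0.01)
})

test_that("planted chr7 gain is detectable at the 0.999 level with 200+ genes", {
  sim <- simulate_counts(simulation_config(
    n_cells = 400, n_genes = 4000,
    population_fractions = c(CAF = 0.5, malignant = 0.5), seed = 11))
  ann <- sim$gene_annotation
  chr7 <- ann$gene[ann$chromosome == "7"]
  expect_gte(length(chr7), 200)
  norm <- log_normalize(sim$counts)
  mal <- sim$truth_labels == "malignant"
  per_cell <- Matrix::rowMeans(norm[, chr7])
  tt <- t.test(per_cell[mal], per_cell[!mal], alternative = "greater")
  expect_lt(tt$p.value, 0.001)
})

test_that("bulk profile plants straddle the crosstalk thresholds as declared", {
  db <- load_lr_database(lr_fixture_path())
  prof <- simulate_bulk_profiles(db, n_ab = 10, n_ba = 7, seed = 2)
  truth <- prof$truth
  ab <- truth$status == "pass" & truth$direction == "A->B"
  expect_identical(sum(ab), 10L)
  expect_true(all(prof$A$fpkm[truth$ligand[ab]] > 0.05))
  expect_true(all(prof$B$counts[truth$receptor[ab]] > 10))
  at <- truth$status == "at_threshold"
  expect_true(all(prof$A$fpkm[truth$ligand[at]] == 0.05))
  expect_true(all(prof$B$counts[truth$receptor[at]] == 10))
  lf <- truth$status == "ligand_fail"
  expect_true(all(prof$A$fpkm[truth$ligand[lf]] < 0.05))
})

test_that("spatial maps are normalized and colocalization shows in correlation", {
  map <- simulate_spatial_map(32, c("CAF", "MES", "neuron"),
                              colocalized_pairs = list(c("CAF", "MES")),
                              seed = 7)
  for (ct in c("CAF", "MES", "neuron")) {
    expect_true(all(map[[ct]] >= 0 & map[[ct]] <= 1))
  }
  r2_pair <- spatial_correlation(map, "CAF", "MES")$r_squared
  r2_indep <- spatial_correlation(map, "CAF", "neuron")$r_squared
  expect_gt(r2_pair, r2_indep)
  # self-pair is trivially identical
  expect_equal(spatial_correlation(map, "CAF", "CAF")$r_squared, 1)
  expect_error(simulate_spatial_map(8, c("A", "B"),
                                    colocalized_pairs = list(c("A", "Z"))),
               "unknown cell type")
  expect_error(simulate_spatial_map(3, "A"), ">= 4")
})
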