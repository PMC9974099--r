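#' Run the full CAF-identification pipeline
#'
#' Orchestrates simulate (or read) -> QC -> log-normalize -> CAF score ->
#' CNV -> classify on one configuration, writing intermediate artifacts and
#' a machine-readable JSON report. One seed governs every stochastic stage;
#' rerunning with the same config and seed reproduces the report exactly.
#'
#' The `config` list mirrors the stage interfaces; every block is optional:
#' \describe{
#'   \item{simulate}{arguments for [simulation_config()]; omit and give
#'     `input` to read data instead.}
#'   \item{input}{path to a counts directory/TSV plus `annotation` TSV.}
#'   \item{qc}{`mito_max`, `umi_min`, `umi_max`.}
#'   \item{score}{`bandwidth`, `cutoff`.}
#'   \item{cnv}{`bin_size`, `smooth_span`, `gain_min`, `loss_max`,
#'     `min_bin_fraction`; set `config$cnv <- FALSE` to skip the CNV stage
#'     (labels are then produced without the malignant rule).}
#' }
#'
#' @param config Nested list of stage parameters (see Details).
#' @param out_dir Output directory; intermediate TSV/JSON artifacts are
#'   written here. `NULL` keeps everything in memory.
#' @param seed Optional integer overriding `config$simulate$seed`.
#' @return A `pipeline_report` list: parameter echo, per-stage summaries,
#'   composition, score summary, and (for simulated input) recovery metrics
#'   against truth labels.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  known <- c("simulate", "input", "qc", "score", "cnv")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- input stage ----------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    stage_msg("input", "reading counts from ", config$input$counts)
    m <- read_counts(config$input$counts)
    ann <- read_gene_annotation(config$input$annotation)
    sim_cfg <- NULL
  } else {
    sim_args <- if (is.null(config$simulate)) list() else config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    sim_cfg <- do.call(simulation_config, sim_args)
    stage_msg("simulate", sim_cfg$n_cells, " cells, seed ", sim_cfg$seed)
    sim <- simulate_counts(sim_cfg)
    m <- sim$counts
    ann <- sim$gene_annotation
    truth <- sim$truth_labels
    if (!is.null(out_dir))
      write_counts_10x(m, file.path(out_dir, "counts"), annotation = ann,
                       labels = truth)
  }

  # --- qc -------------------------------------------------------------
  qc_par <- modifyList(list(mito_max = 0.20, umi_min = 200,
                            umi_max = 20000),
                       if (is.list(config$qc)) config$qc else list())
  qc <- compute_cell_qc(m)
  mf <- qc_filter(m, qc, qc_par$mito_max, qc_par$umi_min, qc_par$umi_max)
  qc_summary <- attr(mf, "qc_summary")
  stage_msg("qc", qc_summary[["n_retained"]], "/", qc_summary[["n_input"]],
            " cells retained")
  if (!is.null(out_dir)) {
    qc$pass <- qc$cell %in% rownames(mf)
    utils::write.table(qc, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  norm <- log_normalize(mf)

  # --- scoring --------------------------------------------------------
  sc_par <- modifyList(list(bandwidth = 1.0, cutoff = 0.6),
                       if (is.list(config$score)) config$score else list())
  scores <- panel_probability(norm, gbm_marker_panels()$caf,
                              h = sc_par$bandwidth)
  stage_msg("score", "median CAF probability ",
            signif(stats::median(scores$scores$p), 3))

  # --- cnv ------------------------------------------------------------
  cnv_skipped <- isFALSE(config$cnv)
  malignant <- NULL
  cnv_par <- modifyList(list(bin_size = 1e6, smooth_span = 5e6,
                             gain_min = 0.15, loss_max = -0.15,
                             min_bin_fraction = 0.5),
                        if (is.list(config$cnv)) config$cnv else list())
  if (!cnv_skipped) {
    bins <- bin_genes(ann[ann$chromosome != "MT", ], cnv_par$bin_size)
    profile <- infer_cnv(norm, bins, cnv_par$smooth_span)
    calls <- call_chromosome_events(profile, cnv_par$gain_min,
                                    cnv_par$loss_max,
                                    cnv_par$min_bin_fraction)
    malignant <- is_gbm_malignant(calls)
    stage_msg("cnv", sum(malignant), " cells flagged chr7+/chr10-")
    if (!is.null(out_dir)) {
      utils::write.table(
        data.frame(cell = rownames(calls), chr7_call = calls[, "7"],
                   chr10_call = calls[, "10"],
                   malignant = unname(malignant)),
        file.path(out_dir, "cnv_calls.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  } else {
    stage_msg("cnv", "skipped")
  }

  # --- classify -------------------------------------------------------
  calls_df <- assign_labels(mf, scores, malignant, cutoff = sc_par$cutoff)
  comp <- composition_summary(calls_df)
  stage_msg("classify", paste(sprintf("%s=%.2f", names(comp$fractions),
                                      comp$fractions), collapse = " "))
  stage <- stage_scores(norm, caf_mask = calls_df$label == "CAF")
  if (!is.null(out_dir)) {
    out_tab <- cbind(calls_df, stage_ratio = stage$stage_ratio)
    utils::write.table(out_tab, file.path(out_dir, "celltypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  recovery <- NULL
  if (!is.null(truth)) {
    tr <- truth[rownames(mf)]
    recovery <- list(
      caf_score_auc = score_auc(scores$scores$p, tr == "CAF"),
      composition_error = {
        want <- sim_cfg$population_fractions
        have <- comp$fractions[names(want)]
        have[is.na(have)] <- 0
        max(abs(have - want))
      })
    if (!cnv_skipped && "malignant" %in% names(table(tr))) {
      fm <- flag_metrics(malignant, tr == "malignant")
      recovery$malignant_sensitivity <- unname(fm["sensitivity"])
      recovery$malignant_specificity <- unname(fm["specificity"])
    }
  }

  report <- list(
    tool = paste0("cafid ", as.character(utils::packageVersion("cafid"))),
    seed = if (!is.null(sim_cfg)) sim_cfg$seed else NA,
    parameters = list(qc = qc_par, score = sc_par,
                      cnv = if (cnv_skipped) "skipped" else cnv_par,
                      simulate = if (is.null(sim_cfg)) NULL else
                        sim_config_echo(sim_cfg)),
    stages = list(qc = as.list(qc_summary),
                  cnv = if (cnv_skipped) "skipped" else
                    list(n_malignant = sum(malignant))),
    score_summary = as.list(summary(scores$scores$p)),
    composition = as.list(comp$fractions),
    n_cells = comp$n_cells,
    fraction_caf_late_dominant = attr(stage, "fraction_late_dominant"),
    recovery = recovery)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    jsonlite::write_json(list(fractions = as.list(comp$fractions),
                              n = comp$n_cells),
                         file.path(out_dir, "composition.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

sim_config_echo <- function(cfg) {
  out <- unclass(cfg)
  out$marker_assignments <- lapply(out$marker_assignments, as.list)
  out
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", x$tool, ", seed ", x$seed, "\n", sep = "")
  cat("  cells:", x$n_cells, "\n  composition:\n")
  for (lbl in names(x$composition))
    cat(sprintf("    %-18s %5.1f%%\n", lbl, 100 * x$composition[[lbl]]))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: AUC %.3f, max composition error %.3f\n",
                x$recovery$caf_score_auc, x$recovery$composition_error))
    if (!is.null(x$recovery$malignant_sensitivity))
      cat(sprintf("  malignant flag: sens %.3f, spec %.3f\n",
                  x$recovery$malignant_sensitivity,
                  x$recovery$malignant_specificity))
  }
  invisible(x)
}

#' Reference percentages for the GSE132825 serial-trypsinization dataset
#'
#' Headline percentages reported for the serially trypsinized glioblastoma
#' cells deposited as GEO accession GSE132825, used by
#' [validate_against_accession()] as the comparison column.
#'
#' @return Named numeric vector of percentages.
#' @export
gbm_caf_reference_values <- function() {
  c(negative_selection_retained_pct = 75.2,
    acta2_prevalence_pct = 73.8,
    col1a1_prevalence_pct = 96.5,
    panel_coverage_retained_pct = 86.5,
    panel_coverage_total_pct = 65.1,
    composition_caf_pct = 52,
    composition_myeloid_pct = 22,
    composition_malignant_pct = 20,
    composition_oligodendrocyte_pct = 6)
}

#' Compare a downloaded expression matrix against reference percentages
#'
#' Recomputes the headline percentages of the CAF-identification workflow
#' (negative-selection retention, ACTA2/COL1A1 prevalence, CAF-panel
#' coverage, cell-type composition) on a user-provided matrix and prints
#' them beside the reference values for the GSE132825 dataset
#' ([gbm_caf_reference_values()]). Intended for validation against the
#' deposited accession, which must be downloaded by the user; agreement is
#' reported, not asserted, because the exact upstream preprocessing of the
#' deposited matrix is not fully specified.
#'
#' @param matrix_path Counts directory or dense TSV for [read_counts()].
#' @param annotation_path Gene annotation TSV (gene, chromosome, start), or
#'   `NULL` to skip CNV-based malignancy (composition is then computed
#'   without the malignant rule).
#' @param detect_min Detection threshold for prevalence/selection
#'   (default 1).
#' @param cutoff CAF score cutoff (default 0.6).
#' @return `data.frame` with columns `metric`, `computed`, `reference`.
#' @export
validate_against_accession <- function(matrix_path, annotation_path = NULL,
                                       detect_min = 1L, cutoff = 0.6) {
  m <- read_counts(matrix_path)
  qc <- compute_cell_qc(m)
  mf <- qc_filter(m, qc)
  norm <- log_normalize(mf)
  panels <- gbm_marker_panels()
  retained <- negative_selection(mf, detect_min = detect_min)
  scores <- panel_probability(norm, panels$caf)

  malignant <- NULL
  if (!is.null(annotation_path)) {
    ann <- read_gene_annotation(annotation_path)
    ann <- ann[normalize_chrom(ann$chromosome) != "MT", , drop = FALSE]
    if (!all(c("7", "10") %in% normalize_chrom(ann$chromosome))) {
      message("annotation lacks chr7/chr10; CNV comparison skipped")
    } else {
      bins <- bin_genes(ann)
      profile <- infer_cnv(norm, bins)
      malignant <- is_gbm_malignant(call_chromosome_events(profile))
    }
  }
  calls <- assign_labels(mf, scores, malignant, cutoff = cutoff,
                         detect_min = detect_min)
  comp <- composition_summary(calls)
  pct <- function(x) 100 * x
  frac_of <- function(lbl) {
    f <- comp$fractions[lbl]
    if (is.na(f)) 0 else unname(f)
  }
  computed <- c(
    negative_selection_retained_pct = pct(mean(retained)),
    acta2_prevalence_pct = pct(marker_prevalence(mf, "ACTA2", detect_min,
                                                 within = retained)),
    col1a1_prevalence_pct = pct(marker_prevalence(mf, "COL1A1", detect_min,
                                                  within = retained)),
    panel_coverage_retained_pct = pct(panel_coverage(mf,
                                                     panels$caf$positives,
                                                     detect_min,
                                                     within = retained)),
    panel_coverage_total_pct = pct(panel_coverage(mf, panels$caf$positives,
                                                  detect_min)),
    composition_caf_pct = pct(frac_of("CAF")),
    composition_myeloid_pct = pct(frac_of("myeloid")),
    composition_malignant_pct = pct(frac_of("malignant")),
    composition_oligodendrocyte_pct = pct(frac_of("oligodendrocyte")))
  ref <- gbm_caf_reference_values()
  out <- data.frame(metric = names(computed),
                    computed = round(unname(computed), 1),
                    reference = unname(ref[names(computed)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
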