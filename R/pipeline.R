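## End-to-end pipeline orchestration.  Stage order is fixed: load/validate,
## per-mode drift correction, per-mode filter cascade, mode concatenation,
## FTOE derivation and pairing, Pearson screening, multivariate structure
## (PCA + Ward on significant features), pathway enrichment.  The run is a
## pure function of (inputs, config, seed); the JSON report serializes all
## floats at 12 significant digits.

#' Run the full post-processing pipeline
#'
#' @param config a [pipeline_config()].
#' @param pos,neg peak-table file paths (positive / negative mode).
#' @param meta_pos,meta_neg injection metadata paths (if one metadata sheet
#'   serves both modes, pass it twice).
#' @param clinical clinical sheet path (patient_id, timepoint, sao2, sco2).
#' @param pathways pathway library path (default: packaged library).
#' @param drugs drug list path (default: packaged list).
#' @param out optional output directory; when given, the JSON report and
#'   stage tables are written there.
#' @return the report (list), invisibly when `out` is given.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         pos, neg, meta_pos, meta_neg, clinical,
                         pathways = NULL, drugs = NULL, out = NULL) {
  stage_log <- character()
  note <- function(fmt, ...) {
    stage_log <<- c(stage_log, sprintf(fmt, ...))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .fail("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  set.seed(config$rng_seed)

  lib <- if (is.null(pathways)) default_pathway_library()
         else read_pathway_library(pathways)
  drug_df <- if (is.null(drugs)) default_drug_list() else read_drug_list(drugs)
  tabs <- run_stage("load", list(
    pos = read_feature_table(pos, meta_pos),
    neg = read_feature_table(neg, meta_neg)))
  cl <- run_stage("load", derive_oximetry(
    utils::read.table(clinical, header = TRUE, sep = .sniff_sep(clinical),
                      stringsAsFactors = FALSE, quote = "")))
  counts <- list()
  for (m in c("pos", "neg")) {
    counts[[paste0("n_input_", m)]] <- nrow(tabs[[m]]$features)
    note("load:%s features=%d injections=%d", m, nrow(tabs[[m]]$features),
         nrow(tabs[[m]]$injections))
  }

  corr_reports <- list()
  for (m in c("pos", "neg")) {
    cb <- run_stage("drift_correction", correct_batch(tabs[[m]], config))
    tabs[[m]] <- cb$table
    corr_reports[[m]] <- cb$report
    note("drift_correction:%s median_pre_rsd=%.6g median_post_rsd=%.6g", m,
         stats::median(cb$report$pre_rsd), stats::median(cb$report$post_rsd))
  }

  filt_reports <- list()
  for (m in c("pos", "neg")) {
    fc <- run_stage("filter_cascade",
                    apply_filter_cascade(tabs[[m]], drug_df, config))
    tabs[[m]] <- fc$table
    filt_reports[[m]] <- fc$report
    counts[[paste0("n_surviving_", m)]] <- fc$report$n_surviving
    note("filter_cascade:%s in=%d blank=%d rsd=%d drug=%d out=%d", m,
         fc$report$n_input, fc$report$n_removed_blank,
         fc$report$n_removed_rsd, fc$report$n_removed_drug,
         fc$report$n_surviving)
  }

  combined <- run_stage("concatenate", concatenate_modes(tabs$pos, tabs$neg))
  note("concatenate features=%d", nrow(combined$features))

  ftoe <- run_stage("ftoe_pairing", match_ftoe(combined, cl))
  screen <- run_stage("correlation_screen",
                      pearson_with_ftoe(combined, ftoe, config))
  n_sig <- sum(screen$class != "nonsignificant")
  note("correlation_screen significant=%d of %d", n_sig, nrow(screen))

  multivar <- run_stage("multivariate", {
    st <- study_idx(combined)
    x <- combined$intensities[, st, drop = FALSE]
    colnames(x) <- combined$injections$injection_id[st]
    pca <- clust <- NULL
    if (nrow(x) >= 2L) {
      z_all <- autoscale(log1p(x))
      pca <- pca_scores(z_all, n_components = 2L)
      sig_rows <- which(screen$class != "nonsignificant")
      if (length(sig_rows) >= 2L)
        clust <- ward_cluster(z_all[sig_rows, , drop = FALSE], k = 2L)
    }
    list(pca = pca, cluster = clust,
         sample_ids = combined$injections$injection_id[st],
         timepoints = combined$injections$timepoint[st])
  })
  if (!is.null(multivar$pca))
    note("pca ev1=%.6g ev2=%.6g", multivar$pca$explained_variance[1],
         multivar$pca$explained_variance[2])

  enr <- run_stage("enrichment", enrich(screen, lib, config))
  note("enrichment pathways=%d top=%s", nrow(enr),
       if (nrow(enr)) enr$pathway_id[1] else "none")

  report <- list(
    config = unclass(config),
    stage_log = stage_log,
    counts = counts,
    correction = corr_reports,
    filters = lapply(filt_reports, function(r)
      r[c("n_input", "n_removed_blank", "n_removed_rsd", "n_removed_drug",
          "n_surviving")]),
    correlation = screen,
    pca = if (!is.null(multivar$pca))
      list(scores = as.data.frame(multivar$pca$scores),
           explained_variance = multivar$pca$explained_variance,
           sample_ids = multivar$sample_ids,
           timepoints = multivar$timepoints) else NULL,
    cluster = if (!is.null(multivar$cluster))
      list(labels = unname(multivar$cluster$labels),
           sample_ids = multivar$sample_ids) else NULL,
    enrichment = enr)

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         dataframe = "columns", digits = I(12),
                         auto_unbox = TRUE, na = "null", pretty = TRUE)
    utils::write.table(screen, file.path(out, "correlation_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (m in c("pos", "neg"))
      utils::write.table(corr_reports[[m]],
                         file.path(out, paste0("correction_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}
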