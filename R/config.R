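#' Pipeline configuration
#'
#' Bundles every tunable threshold of the post-processing pipeline.  The
#' defaults are the published settings of the workflow this package
#' implements: blank exclusion below 5x the blank signal, QC RSD% cut at
#' 20% (inclusive), 10 mDa drug-ion tolerance, 10 ppm annotation accuracy,
#' top-10% significant-peak fraction for enrichment, and the |r| > 0.5 /
#' p < 0.05 Pearson screening rule.  The SVR grids cover epsilon 2.5-7.5
#' (percent of the QC median, 5 even steps) and gamma 1-1e5 (decade steps).
#'
#' @param blank_ratio study/blank signal ratio below which a feature is a
#'   blank contaminant (strict `<`).
#' @param rsd_threshold_percent QC RSD% cut, inclusive (`>=` removes).
#' @param drug_mz_tolerance absolute m/z tolerance (Th) for drug-ion removal.
#' @param annotation_ppm mass accuracy (ppm) for pathway annotation.
#' @param sig_top_fraction fraction of features (smallest p) fed to
#'   enrichment as significant.
#' @param corr_p_threshold,corr_r_threshold Pearson screening rule
#'   (`p < corr_p_threshold` and `|r| > corr_r_threshold`, both strict).
#' @param svr_epsilon_grid,svr_gamma_grid grids searched by leave-one-out
#'   cross-validation when fitting the per-feature QC drift model.
#' @param permutations resampling count for the enrichment null.
#' @param rng_seed seed making the whole pipeline deterministic.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(blank_ratio = 5,
                            rsd_threshold_percent = 20,
                            drug_mz_tolerance = 0.010,
                            annotation_ppm = 10,
                            sig_top_fraction = 0.10,
                            corr_p_threshold = 0.05,
                            corr_r_threshold = 0.5,
                            svr_epsilon_grid = seq(2.5, 7.5, length.out = 5),
                            svr_gamma_grid = 10^(0:5),
                            permutations = 1000,
                            rng_seed = 1L) {
  cfg <- list(blank_ratio = blank_ratio,
              rsd_threshold_percent = rsd_threshold_percent,
              drug_mz_tolerance = drug_mz_tolerance,
              annotation_ppm = annotation_ppm,
              sig_top_fraction = sig_top_fraction,
              corr_p_threshold = corr_p_threshold,
              corr_r_threshold = corr_r_threshold,
              svr_epsilon_grid = sort(svr_epsilon_grid),
              svr_gamma_grid = sort(svr_gamma_grid),
              permutations = as.integer(permutations),
              rng_seed = as.integer(rng_seed))
  for (nm in c("blank_ratio", "rsd_threshold_percent", "drug_mz_tolerance",
               "annotation_ppm", "corr_p_threshold", "corr_r_threshold"))
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      .fail("config field '%s' must be a single positive number", nm)
  if (cfg$sig_top_fraction <= 0 || cfg$sig_top_fraction > 1)
    .fail("sig_top_fraction must lie in (0, 1]")
  if (any(cfg$svr_epsilon_grid <= 0) || any(cfg$svr_gamma_grid <= 0))
    .fail("SVR grids must be strictly positive")
  if (cfg$permutations < 100L)
    .fail("permutations must be >= 100")
  structure(cfg, class = "pipeline_config")
}
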