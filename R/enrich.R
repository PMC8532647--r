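## Mummichog-style "MS peaks to pathways" enrichment: tentative m/z ->
## compound annotation at a ppm tolerance, top-fraction significant peak
## selection, per-pathway EASE-adjusted Fisher right-tail scoring, and a
## resampling null whose pooled -log10 p values are gamma-fit to yield
## adjusted p-values (v1 semantics of the mummichog algorithm).

#' Read a pathway library
#'
#' TSV with columns `pathway_id`, `name`, `compound_code`, `neutral_mass`
#' (one row per pathway-compound pair; a compound may appear in several
#' pathways).
#'
#' @param path file path.
#' @return data.frame of class `pathway_library`.
#' @export
read_pathway_library <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         stringsAsFactors = FALSE, quote = "")
  need <- c("pathway_id", "name", "compound_code", "neutral_mass")
  if (!all(need %in% names(d)))
    .fail("pathway library '%s' needs columns %s", path,
          paste(need, collapse = ", "))
  if (any(d$neutral_mass <= 0)) .fail("compound masses must be > 0")
  class(d) <- c("pathway_library", class(d))
  d
}

#' Packaged pathway library / drug list
#'
#' Convenience accessors for the small fixture files shipped with the
#' package (four sugar/redox pathways with compound masses derived from
#' molecular formulas, and a neonatal drug list).
#'
#' @return data.frame.
#' @export
default_pathway_library <- function() {
  read_pathway_library(system.file("extdata", "pathway_library.tsv",
                                   package = "oxiswitch", mustWork = TRUE))
}

#' @rdname default_pathway_library
#' @export
default_drug_list <- function() {
  read_drug_list(system.file("extdata", "drug_list.tsv",
                             package = "oxiswitch", mustWork = TRUE))
}

#' Annotate feature m/z values against a compound library
#'
#' A feature matches a compound iff `|mz - ion| / ion * 1e6 <= ppm` for any
#' adduct ion of the feature's ionization mode ([M+H]+/[M+Na]+/[M+K]+ or the
#' negative-mode equivalents; no isotopologues).  The mapping is
#' many-to-many.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `mode`.
#' @param library pathway library data.frame (see
#'   [read_pathway_library()]).
#' @param ppm mass accuracy, parts per million.
#' @return data.frame: `feature_id`, `compound_code`, `adduct`, `ppm_error`.
#' @export
annotate_mz <- function(features, library, ppm = 10) {
  if (ppm <= 0) .fail("ppm must be > 0")
  compounds <- unique(library[c("compound_code", "neutral_mass")])
  empty <- data.frame(feature_id = character(), compound_code = character(),
                      adduct = character(), ppm_error = numeric())
  if (!nrow(compounds) || !nrow(features)) return(empty)
  out <- vector("list", 2)
  for (mode in c("positive", "negative")) {
    rows <- which(features$mode == mode)
    if (!length(rows)) next
    ions <- lapply(compounds$neutral_mass, adduct_mz, mode = mode)
    ion_mz <- unlist(ions, use.names = FALSE)
    ion_code <- rep(compounds$compound_code, each = 3L)
    ion_lab <- unlist(lapply(ions, names), use.names = FALSE)
    rel <- abs(outer(features$mz[rows], ion_mz, "-")) /
      rep(ion_mz, each = length(rows)) * 1e6
    hit <- which(rel <= ppm, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[mode]] <- data.frame(
      feature_id = features$feature_id[rows][hit[, 1]],
      compound_code = ion_code[hit[, 2]],
      adduct = ion_lab[hit[, 2]],
      ppm_error = rel[hit])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res <- unique(res[c("feature_id", "compound_code", "adduct", "ppm_error")])
  rownames(res) <- NULL
  res
}

#' Select the top fraction of features by p-value
#'
#' The `ceiling(fraction * n)` features with smallest p; features tied with
#' the boundary p-value are all included.
#'
#' @param pvalues numeric vector (may be named).
#' @param fraction fraction in (0, 1].
#' @return integer indices of the selected features.
#' @export
select_top_fraction <- function(pvalues, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) .fail("fraction must lie in (0, 1]")
  n <- length(pvalues)
  if (!n) return(integer())
  m <- ceiling(fraction * n)
  cutoff <- sort(pvalues)[m]
  which(pvalues <= cutoff)
}

#' EASE-adjusted Fisher right-tail p-value
#'
#' The right-tail hypergeometric probability with one success removed from
#' the observed overlap (the conservative EASE score):
#' `P(X >= k - 1)` for X hypergeometric with population `N`, `K` successes
#' and `n` draws.  `k = 0` gives p = 1.
#'
#' @param k observed significant compounds in the pathway.
#' @param K annotated compounds in the pathway.
#' @param n significant compounds overall.
#' @param N annotated compounds overall.
#' @return p-value.
#' @export
#' @examples
#' pathway_ease_p(5, 5, 6, 20)  # 540/38760
pathway_ease_p <- function(k, K, n, N) {
  if (k > K || k > n || K > N || n > N || min(k, K, n, N) < 0)
    .fail("inconsistent contingency counts (k=%s K=%s n=%s N=%s)", k, K, n, N)
  if (k == 0) return(1)
  stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

## per-pathway significant-hit counts for a given significant compound set
.pathway_counts <- function(library, annotated_codes, sig_codes) {
  pws <- unique(library[c("pathway_id", "name")])
  pws$n_hits <- vapply(pws$pathway_id, function(id) {
    length(intersect(library$compound_code[library$pathway_id == id],
                     annotated_codes))
  }, integer(1))
  pws$n_sig_hits <- vapply(pws$pathway_id, function(id) {
    length(intersect(library$compound_code[library$pathway_id == id],
                     sig_codes))
  }, integer(1))
  pws
}

#' Permutation-gamma adjustment of pathway p-values
#'
#' Repeats `permutations` times: draw a uniform random feature subset of the
#' observed significant-set size, recompute every pathway's EASE p, pool the
#' positive `-log10` null p-values across pathways and permutations, fit a
#' gamma distribution by maximum likelihood (location fixed at 0), and
#' return `adj_p = P(Gamma >= -log10(raw_p))` per pathway.  A degenerate
#' null falls back to the empirical tail with a flag.
#'
#' @param observed data.frame with `pathway_id` and `raw_p`.
#' @param annotation feature-compound map from [annotate_mz()].
#' @param library pathway library.
#' @param feature_ids all feature ids eligible for resampling.
#' @param n_sig size of the significant feature set.
#' @param permutations number of resamples (>= 100).
#' @param seed RNG seed (local to this call).
#' @return `observed` with columns `adj_p` and `null_model`
#'   (`"gamma"` or `"empirical"`).
#' @export
permutation_gamma_adjust <- function(observed, annotation, library,
                                     feature_ids, n_sig,
                                     permutations = 1000, seed = 1L) {
  if (permutations < 100L) .fail("permutations must be >= 100")
  feature_ids <- sort(feature_ids)  # input-order invariance of the resamples
  ann_codes <- unique(annotation$compound_code)
  N <- length(ann_codes)
  pw_codes <- lapply(split(library$compound_code, library$pathway_id),
                     function(cc) intersect(unique(cc), ann_codes))
  code_sets <- split(annotation$compound_code, annotation$feature_id)
  null_log <- numeric(0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  n_sig <- min(n_sig, length(feature_ids))
  for (b in seq_len(permutations)) {
    draw <- sample(feature_ids, n_sig)
    sig_codes <- unique(unlist(code_sets[as.character(draw)],
                               use.names = FALSE))
    n <- length(sig_codes)
    ps <- vapply(pw_codes, function(cc) {
      pathway_ease_p(length(intersect(cc, sig_codes)), length(cc), n, N)
    }, numeric(1))
    null_log <- c(null_log, -log10(ps))
  }
  obs_log <- -log10(observed$raw_p)
  pos <- null_log[null_log > 0]
  use_gamma <- length(pos) >= 10L && stats::sd(pos) > 0
  if (use_gamma) {
    fit <- tryCatch(fit_gamma_ml(pos), error = function(e) NULL)
    use_gamma <- !is.null(fit)
  }
  if (use_gamma) {
    adj <- stats::pgamma(obs_log, shape = fit$shape, rate = fit$rate,
                         lower.tail = FALSE)
    observed$null_model <- "gamma"
  } else {
    adj <- vapply(obs_log, function(o)
      (1 + sum(null_log >= o)) / (1 + length(null_log)), numeric(1))
    observed$null_model <- "empirical"
  }
  adj[observed$raw_p >= 1] <- 1
  observed$adj_p <- pmin(adj, 1)
  observed
}

#' Run the full enrichment
#'
#' Annotate the input features, take the top `sig_top_fraction` by p-value,
#' count per-pathway annotated and significant compounds, score each
#' pathway with the EASE right tail, and adjust against the permutation
#' null.  Output is sorted by adjusted then raw p.
#'
#' @param corr_table 4-column-style input: data.frame with `feature_id`,
#'   `mz`, `mode` and `p` (plus anything else, e.g. `rt`).
#' @param library pathway library.
#' @param config a [pipeline_config()].
#' @return data.frame: pathway_id, name, compounds_hit, n_hits, n_sig_hits,
#'   raw_p, adj_p, null_model.
#' @export
enrich <- function(corr_table, library = default_pathway_library(),
                   config = pipeline_config()) {
  need <- c("feature_id", "mz", "mode", "p")
  if (!all(need %in% names(corr_table)))
    .fail("enrichment input needs columns %s", paste(need, collapse = ", "))
  ann <- annotate_mz(corr_table, library, config$annotation_ppm)
  if (!nrow(ann)) {
    warning("no feature annotated against the library; empty result")
    return(data.frame(pathway_id = character(), name = character(),
                      compounds_hit = character(), n_hits = integer(),
                      n_sig_hits = integer(), raw_p = numeric(),
                      adj_p = numeric(), null_model = character()))
  }
  sig_idx <- select_top_fraction(corr_table$p, config$sig_top_fraction)
  sig_ids <- corr_table$feature_id[sig_idx]
  ann_codes <- unique(ann$compound_code)
  sig_codes <- unique(ann$compound_code[ann$feature_id %in% sig_ids])
  counts <- .pathway_counts(library, ann_codes, sig_codes)
  N <- length(ann_codes); n <- length(sig_codes)
  counts$raw_p <- mapply(pathway_ease_p, counts$n_sig_hits, counts$n_hits,
                         MoreArgs = list(n = n, N = N))
  counts$compounds_hit <- vapply(counts$pathway_id, function(id)
    paste(sort(intersect(unique(
      library$compound_code[library$pathway_id == id]), sig_codes)),
      collapse = ";"), character(1))
  counts <- permutation_gamma_adjust(
    counts, ann, library, corr_table$feature_id, length(sig_ids),
    permutations = config$permutations, seed = config$rng_seed)
  counts <- counts[order(counts$adj_p, counts$raw_p, counts$pathway_id), ]
  rownames(counts) <- NULL
  counts[c("pathway_id", "name", "compounds_hit", "n_hits", "n_sig_hits",
           "raw_p", "adj_p", "null_model")]
}
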