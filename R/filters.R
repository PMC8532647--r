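## Post-correction feature exclusion rules, applied in cascade order:
## blank contaminants, irreproducible QC features, drug-derived ions.
## Survivorship is order-independent (each rule looks at disjoint evidence);
## only the per-feature removal *reason* reflects the cascade order.

#' Read a drug list
#'
#' TSV with columns `name` and `neutral_mass` (monoisotopic, Da).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_drug_list <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         stringsAsFactors = FALSE, quote = "")
  if (!all(c("name", "neutral_mass") %in% names(d)))
    .fail("drug list '%s' needs columns name, neutral_mass", path)
  if (any(d$neutral_mass <= 0)) .fail("drug neutral_mass must be > 0")
  d
}

#' Expand a drug into the screened ion set
#'
#' For one ionization mode: the protonated/deprotonated molecule, the Na and
#' K adducts (charge-consistent minus-2H forms in negative mode), plus the
#' first 13C isotopologue of each.
#'
#' @param drug list/row with `name` and `neutral_mass`.
#' @param mode `"positive"` or `"negative"`.
#' @return data.frame with columns `label` and `mz`.
#' @export
expand_drug_ions <- function(drug, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  ions <- adduct_mz(drug$neutral_mass, mode, isotopologues = TRUE)
  data.frame(label = paste(drug$name, names(ions)), mz = unname(ions))
}

#' Blank filter
#'
#' A feature is removed iff its median intensity over study samples is
#' strictly below `ratio` times its blank signal, where the blank signal is
#' the maximum over blank injections (conservative).  Features absent from
#' the blanks (blank signal 0) are always kept.
#'
#' @param ft a `feature_table` with >= 1 blank injection.
#' @param ratio study/blank ratio (default 5).
#' @return list(table = filtered table, removed = feature ids).
#' @export
blank_filter <- function(ft, ratio = 5) {
  bl <- blank_idx(ft); st <- study_idx(ft)
  if (!length(bl)) .fail("blank filter needs >= 1 blank injection")
  blank_sig <- apply(ft$intensities[, bl, drop = FALSE], 1, max)
  study_med <- apply(ft$intensities[, st, drop = FALSE], 1, stats::median)
  remove <- blank_sig > 0 & study_med < ratio * blank_sig
  list(table = subset_table(ft, features = !remove),
       removed = ft$features$feature_id[remove])
}

#' QC-RSD filter
#'
#' A feature is removed iff the RSD% of its non-conditioning QC intensities
#' is at or above `threshold` (inclusive).  Features whose QC mean is not
#' positive have undefined (infinite) RSD and are removed.
#'
#' @param ft a `feature_table` with >= 2 non-conditioning QC injections.
#' @param threshold RSD% cut (default 20).
#' @return list(table, removed).
#' @export
rsd_filter <- function(ft, threshold = 20) {
  qc <- qc_idx(ft)
  if (length(qc) < 2L) .fail("RSD filter needs >= 2 non-conditioning QCs")
  rsd <- apply(ft$intensities[, qc, drop = FALSE], 1,
               function(v) as.numeric(rsd_percent(v)))
  remove <- rsd >= threshold
  list(table = subset_table(ft, features = !remove),
       removed = ft$features$feature_id[remove], rsd = rsd)
}

#' Drug-ion filter
#'
#' A feature is removed iff its m/z lies strictly within `tol` (Th) of any
#' expanded drug ion of its own ionization mode (adducts and first 13C
#' isotopologues; retention time plays no role).
#'
#' @param ft a `feature_table`.
#' @param drugs data.frame with `name`, `neutral_mass` (see
#'   [read_drug_list()]).
#' @param tol absolute m/z tolerance, Th (default 0.010).
#' @return list(table, removed, matches) where `matches` names the matched
#'   ion and m/z delta per removed feature.
#' @export
drug_filter <- function(ft, drugs, tol = 0.010) {
  if (tol < 0) .fail("tol must be >= 0")
  if (is.null(drugs) || !nrow(drugs)) {
    warning("empty drug list: drug filter is a no-op")
    return(list(table = ft, removed = character(),
                matches = data.frame(feature_id = character(),
                                     matched_ion = character(),
                                     delta_mz = numeric())))
  }
  remove <- logical(nrow(ft$features))
  match_ion <- character(nrow(ft$features))
  match_d <- rep(NA_real_, nrow(ft$features))
  for (mode in unique(ft$features$mode)) {
    ions <- do.call(rbind, lapply(seq_len(nrow(drugs)), function(i)
      expand_drug_ions(drugs[i, ], mode)))
    rows <- which(ft$features$mode == mode)
    d <- abs(outer(ft$features$mz[rows], ions$mz, "-"))
    hit <- d < tol
    any_hit <- rowSums(hit) > 0
    remove[rows] <- any_hit
    best <- apply(d, 1, which.min)
    match_ion[rows] <- ions$label[best]
    match_d[rows] <- d[cbind(seq_along(rows), best)]
  }
  list(table = subset_table(ft, features = !remove),
       removed = ft$features$feature_id[remove],
       matches = data.frame(feature_id = ft$features$feature_id[remove],
                            matched_ion = match_ion[remove],
                            delta_mz = match_d[remove]))
}

#' Apply the full filter cascade
#'
#' Blank filter, then QC-RSD filter, then drug-ion filter.  The surviving
#' set does not depend on the order; the reason recorded for a removed
#' feature is the first rule that triggered.
#'
#' @param ft a `feature_table`.
#' @param drugs drug list data.frame.
#' @param config a [pipeline_config()].
#' @return list with `table` (survivors) and `report` (class
#'   `filter_report`: counts plus per-feature reason).
#' @export
apply_filter_cascade <- function(ft, drugs, config = pipeline_config()) {
  n_input <- nrow(ft$features)
  b <- blank_filter(ft, config$blank_ratio)
  r <- rsd_filter(b$table, config$rsd_threshold_percent)
  d <- drug_filter(r$table, drugs, config$drug_mz_tolerance)
  reasons <- rbind(
    data.frame(feature_id = b$removed,
               reason = rep("blank", length(b$removed))),
    data.frame(feature_id = r$removed,
               reason = rep("rsd", length(r$removed))),
    data.frame(feature_id = d$removed,
               reason = rep("drug", length(d$removed))))
  report <- structure(
    list(n_input = n_input,
         n_removed_blank = length(b$removed),
         n_removed_rsd = length(r$removed),
         n_removed_drug = length(d$removed),
         n_surviving = nrow(d$table$features),
         reasons = reasons,
         drug_matches = d$matches),
    class = "filter_report")
  stopifnot(report$n_input == report$n_surviving + nrow(reasons))
  list(table = d$table, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d in -> %d out (blank %d, rsd %d, drug %d)\n",
    x$n_input, x$n_surviving, x$n_removed_blank, x$n_removed_rsd,
    x$n_removed_drug))
  invisible(x)
}
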