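## Peak-table container: features x injections intensity matrix plus
## per-feature (m/z, RT, ionization mode) and per-injection metadata.
## Zero intensity means "absent/filled": gap filling happens upstream of
## this package, so zeros are treated as observed values by all statistics.

INJECTION_ROLES <- c("study", "qc", "blank", "conditioning")
TIMEPOINT_LEVELS <- c("pre", "5min", "6h", "24h", "48h", "72h", "96h")

#' Construct a peak table
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`, `mode`.
#' @param injections data.frame with columns `injection_id`, `order`,
#'   `role` (one of study/qc/blank/conditioning) and, for study injections,
#'   `patient_id` and `timepoint`.
#' @param intensities numeric matrix, rows = features, columns = injections,
#'   nonnegative; 0 means not detected / gap-filled.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(features, injections, intensities) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  ft <- structure(
    list(features = as.data.frame(features),
         injections = as.data.frame(injections),
         intensities = intensities),
    class = "feature_table")
  validate_feature_table(ft)
}

#' Validate a peak table's invariants
#'
#' Checks matrix dimensions, id uniqueness, nonnegative intensities, m/z and
#' RT ranges, known roles, unique injection orders, and that study
#' injections carry patient and timepoint labels.  Errors name the first
#' offending row.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly checked.
#' @export
validate_feature_table <- function(ft) {
  fe <- ft$features; inj <- ft$injections; x <- ft$intensities
  need_f <- c("feature_id", "mz", "rt", "mode")
  if (!all(need_f %in% names(fe)))
    .fail("feature sheet must have columns %s", paste(need_f, collapse = ", "))
  need_i <- c("injection_id", "order", "role")
  if (!all(need_i %in% names(inj)))
    .fail("injection sheet must have columns %s", paste(need_i, collapse = ", "))
  if (nrow(x) != nrow(fe) || ncol(x) != nrow(inj))
    .fail("intensity matrix is %d x %d but there are %d features and %d injections",
          nrow(x), ncol(x), nrow(fe), nrow(inj))
  if (anyDuplicated(fe$feature_id))
    .fail("duplicate feature_id '%s'", fe$feature_id[duplicated(fe$feature_id)][1])
  if (anyDuplicated(inj$injection_id))
    .fail("duplicate injection_id '%s'",
          inj$injection_id[duplicated(inj$injection_id)][1])
  if (anyDuplicated(inj$order))
    .fail("duplicate injection order %s", inj$order[duplicated(inj$order)][1])
  bad <- which(!(fe$mz > 0))
  if (length(bad)) .fail("feature '%s': mz must be > 0", fe$feature_id[bad[1]])
  bad <- which(fe$rt < 0)
  if (length(bad)) .fail("feature '%s': rt must be >= 0", fe$feature_id[bad[1]])
  bad <- which(!fe$mode %in% c("positive", "negative"))
  if (length(bad))
    .fail("feature '%s': unknown ionization mode '%s'",
          fe$feature_id[bad[1]], fe$mode[bad[1]])
  bad <- which(!inj$role %in% INJECTION_ROLES)
  if (length(bad))
    .fail("injection '%s': unknown role '%s'",
          inj$injection_id[bad[1]], inj$role[bad[1]])
  if (anyNA(x) || any(x < 0)) {
    idx <- which(is.na(x) | x < 0, arr.ind = TRUE)[1, ]
    .fail("negative or missing intensity at feature '%s', injection '%s'",
          fe$feature_id[idx[1]], inj$injection_id[idx[2]])
  }
  study <- inj$role == "study"
  if (any(study)) {
    if (is.null(inj$patient_id) || is.null(inj$timepoint) ||
        any(is.na(inj$patient_id[study])) || any(is.na(inj$timepoint[study])) ||
        any(!nzchar(inj$patient_id[study])))
      .fail("study injections must carry patient_id and timepoint")
  }
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  roles <- table(factor(x$injections$role, INJECTION_ROLES))
  cat(sprintf("feature_table: %d features x %d injections (%s)\n",
              nrow(x$features), nrow(x$injections),
              paste(sprintf("%s=%d", names(roles), roles), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

## internal role helpers -----------------------------------------------------
injection_idx <- function(ft, role, include_conditioning = FALSE) {
  i <- ft$injections$role %in% role
  if (!include_conditioning) i <- i & ft$injections$role != "conditioning"
  which(i)
}
study_idx <- function(ft) which(ft$injections$role == "study")
qc_idx <- function(ft) which(ft$injections$role == "qc")
blank_idx <- function(ft) which(ft$injections$role == "blank")

#' Subset a peak table
#'
#' @param ft a `feature_table`.
#' @param features optional row index (logical/integer) on features.
#' @param injections optional column index on injections.
#' @return the subset `feature_table`.
#' @export
subset_table <- function(ft, features = NULL, injections = NULL) {
  if (is.null(features)) features <- seq_len(nrow(ft$features))
  if (is.null(injections)) injections <- seq_len(nrow(ft$injections))
  feature_table(ft$features[features, , drop = FALSE],
                ft$injections[injections, , drop = FALSE],
                ft$intensities[features, injections, drop = FALSE])
}

#' Read a peak table and its injection metadata
#'
#' The peak table is CSV or TSV (delimiter sniffed from the header row) with
#' one row per feature: columns `feature_id`, `mz`, `rt`, `mode`, then one
#' intensity column per injection id.  The metadata sheet has columns
#' `injection_id`, `order`, `role`, `patient_id`, `timepoint`.
#' Conditioning injections are retained but flagged by their role; they are
#' excluded from all statistics downstream.
#'
#' @param path peak-table file.
#' @param metadata_path injection metadata file.
#' @return validated `feature_table`.
#' @export
read_feature_table <- function(path, metadata_path) {
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("feature_id", "mz", "rt", "mode")
  if (!all(need %in% names(tab)))
    .fail("peak table '%s' lacks columns %s", path,
          paste(setdiff(need, names(tab)), collapse = ", "))
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = .sniff_sep(metadata_path),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", na.strings = c("NA", ""))
  inj_cols <- setdiff(names(tab), need)
  missing <- setdiff(inj_cols, meta$injection_id)
  if (length(missing))
    .fail("injections %s in peak table have no metadata row",
          paste(missing, collapse = ", "))
  extra <- setdiff(meta$injection_id, inj_cols)
  if (length(extra))
    .fail("metadata rows %s have no intensity column",
          paste(extra, collapse = ", "))
  meta <- meta[match(inj_cols, meta$injection_id), , drop = FALSE]
  rownames(meta) <- NULL
  x <- as.matrix(tab[, inj_cols, drop = FALSE])
  rownames(x) <- NULL
  feature_table(tab[, need], meta, x)
}

#' Write a peak table (and optionally its metadata)
#'
#' Values are serialized at full double precision (17 significant digits) so
#' that a write/read round trip reproduces the table bit-faithfully.
#'
#' @param ft a `feature_table`.
#' @param path output peak-table file (`.csv` writes commas, else tabs).
#' @param metadata_path optional metadata output file (TSV).
#' @export
write_feature_table <- function(ft, path, metadata_path = NULL) {
  validate_feature_table(ft)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  num <- function(v) sprintf("%.17g", v)
  x <- ft$intensities
  m <- matrix(num(x), nrow = nrow(x), ncol = ncol(x),
              dimnames = list(NULL, ft$injections$injection_id))
  out <- cbind(ft$features["feature_id"],
               data.frame(mz = num(ft$features$mz), rt = num(ft$features$rt),
                          mode = ft$features$mode,
                          stringsAsFactors = FALSE)[seq_len(nrow(x)), ,
                                                    drop = FALSE],
               as.data.frame(m, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(ft$injections, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  invisible(path)
}

#' Concatenate positive- and negative-mode peak tables feature-wise
#'
#' Both acquisitions cover the same study extracts, so study injections are
#' matched by `patient_id` + `timepoint`; QC, blank and conditioning
#' injections are matched by injection-order rank within their role.  The
#' combined table keeps the positive-mode injection metadata and stacks the
#' feature blocks unchanged.
#'
#' @param pos,neg `feature_table`s acquired in positive / negative mode.
#' @return combined `feature_table`.
#' @export
concatenate_modes <- function(pos, neg) {
  validate_feature_table(pos); validate_feature_table(neg)
  key <- function(ft) {
    i <- ft$injections
    ifelse(i$role == "study",
           paste0("study:", i$patient_id, ":", i$timepoint),
           paste0(i$role, ":", ave(i$order, i$role, FUN = rank)))
  }
  kp <- key(pos); kn <- key(neg)
  miss <- setdiff(kp, kn)
  miss2 <- setdiff(kn, kp)
  if (length(miss) || length(miss2))
    .fail("unmatched injections between modes: %s",
          paste(c(miss, miss2), collapse = ", "))
  if (anyDuplicated(kp)) .fail("duplicate patient/timepoint pairs in table")
  map <- match(kp, kn)
  dup <- intersect(pos$features$feature_id, neg$features$feature_id)
  if (length(dup))
    .fail("feature ids shared between modes (e.g. '%s'); ids must be unique",
          dup[1])
  feature_table(rbind(pos$features, neg$features),
                pos$injections,
                rbind(pos$intensities, neg$intensities[, map, drop = FALSE]))
}
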