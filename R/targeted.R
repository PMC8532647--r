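## Targeted lipid-peroxidation biomarker panel statistics: relative
## responses against deuterated internal standards, exclusion of analytes
## below the limit of quantification in every sample, Wilcoxon rank-sum
## contrasts of each post-procedure timepoint against baseline, and Pearson
## correlation of analyte levels with FTOE.

BIOMARKER_ANALYTES <- c("IsoPs", "Di-homo-IsoPs", "Di-homo-IsoFs",
                        "NeuroFs", "IsoFs", "NeuroPs")

#' Relative response of an analyte
#'
#' Analyte peak area divided by internal-standard peak area; dimensionless
#' and invariant under joint rescaling of both areas.
#'
#' @param analyte_area analyte peak area (>= 0).
#' @param is_area internal-standard peak area (> 0; nonpositive values give
#'   NA flagged via attribute `missing`).
#' @return relative response.
#' @export
relative_response <- function(analyte_area, is_area) {
  out <- ifelse(is_area > 0, analyte_area / is_area, NA_real_)
  if (anyNA(out)) attr(out, "missing") <- which(is.na(out))
  out
}

#' Read a biomarker panel
#'
#' TSV with columns `sample_id`, `patient_id`, `timepoint`, `analyte`,
#' `analyte_area`, `is_area`, `below_loq` (logical).
#'
#' @param path file path.
#' @return data.frame with `relative_response` appended.
#' @export
read_biomarker_panel <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "timepoint", "analyte", "analyte_area", "is_area",
            "below_loq")
  if (!all(need %in% names(d)))
    .fail("panel '%s' needs columns %s", path, paste(need, collapse = ", "))
  d$below_loq <- as.logical(d$below_loq)
  d$relative_response <- c(relative_response(d$analyte_area, d$is_area))
  d
}

#' Exclude analytes below LOQ in all samples
#'
#' An analyte is dropped iff it is flagged below the limit of
#' quantification in every study sample; an analyte quantifiable in even
#' one sample is retained.  Idempotent.
#'
#' @param panel long data.frame with columns `analyte` and `below_loq`.
#' @return list with `panel` (retained rows) and `excluded` (analyte names).
#' @export
loq_exclude <- function(panel) {
  if (!all(c("analyte", "below_loq") %in% names(panel)))
    .fail("panel needs columns analyte, below_loq")
  all_below <- tapply(panel$below_loq, panel$analyte, all)
  excluded <- names(all_below)[all_below %in% TRUE]
  list(panel = panel[!panel$analyte %in% excluded, , drop = FALSE],
       excluded = excluded)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null over all `choose(n1+n2, n1)`
#' group assignments when the combined sample size is <= 12 (ties handled
#' by average ranks, conditioning on the observed values); otherwise the
#' normal approximation with tie and continuity corrections.  The exact
#' two-sided p doubles the smaller tail (capped at 1).
#'
#' @param x,y numeric vectors (>= 2 observations each).
#' @return list with `statistic` (rank sum of `x`), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) .fail("each group needs >= 2 observations")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 + n2 <= 12L) {
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    lo <- mean(sums <= w + 1e-9)
    hi <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = w, p = p, method = method)
}

#' Biomarker changes over time
#'
#' Compares each post-procedure timepoint against baseline per analyte with
#' the two-sided Wilcoxon rank-sum test.  Analytes below LOQ everywhere
#' should be excluded first ([loq_exclude()]); remaining below-LOQ values
#' are kept as reported, or imputed as LOQ/2 when a `loq` column is present
#' and the reported response is missing (imputations flagged).
#'
#' @param panel long data.frame with `analyte`, `timepoint`,
#'   `relative_response` (and optional `loq`, `below_loq`).
#' @param baseline baseline timepoint label (default `"pre"`).
#' @param comparisons timepoints to contrast against baseline (default: all
#'   non-baseline timepoints present).
#' @return data.frame: analyte, timepoint, n_baseline, n_timepoint, p,
#'   method.
#' @export
wilcoxon_over_time <- function(panel, baseline = "pre", comparisons = NULL) {
  if (!nrow(panel)) .fail("empty panel")
  v <- panel$relative_response
  if (!is.null(panel$loq) && !is.null(panel$below_loq)) {
    imp <- panel$below_loq & is.na(v)
    v[imp] <- panel$loq[imp] / 2
  }
  panel$.value <- v
  if (is.null(comparisons))
    comparisons <- setdiff(unique(panel$timepoint), baseline)
  out <- list()
  for (an in unique(panel$analyte)) {
    base <- panel$.value[panel$analyte == an & panel$timepoint == baseline]
    if (!length(base)) .fail("analyte '%s': empty baseline group", an)
    for (tp in comparisons) {
      grp <- panel$.value[panel$analyte == an & panel$timepoint == tp]
      if (!length(grp)) .fail("analyte '%s': empty group at '%s'", an, tp)
      wt <- wilcoxon_rank_sum(grp, base)
      out[[length(out) + 1L]] <- data.frame(
        analyte = an, timepoint = tp, n_baseline = length(base),
        n_timepoint = length(grp), p = wt$p, method = wt$method)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation of analytes with FTOE
#'
#' Per analyte: Pearson r over paired samples with the two-sided t-test
#' p-value; `strong` iff |r| > 0.5 (strict) and p < 0.05.
#'
#' @param panel long data.frame with `analyte`, `sample_id`,
#'   `relative_response`.
#' @param ftoe named numeric vector of FTOE keyed by `sample_id`.
#' @return data.frame: analyte, r, p, n, strong, flag.
#' @export
biomarker_ftoe_correlation <- function(panel, ftoe) {
  out <- list()
  for (an in unique(panel$analyte)) {
    rows <- panel[panel$analyte == an, ]
    f <- ftoe[as.character(rows$sample_id)]
    keep <- stats::complete.cases(rows$relative_response, f)
    v <- rows$relative_response[keep]; f <- f[keep]
    n <- length(v)
    if (n < 3L || stats::sd(v) == 0 || stats::sd(f) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        analyte = an, r = NA_real_, p = NA_real_, n = n, strong = FALSE,
        flag = "constant_or_short")
      next
    }
    r <- stats::cor(v, f)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    out[[length(out) + 1L]] <- data.frame(
      analyte = an, r = r, p = p, n = n,
      strong = abs(r) > 0.5 && p < 0.05, flag = NA_character_)
  }
  do.call(rbind, out)
}
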