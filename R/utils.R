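#' Relative standard deviation in percent
#'
#' RSD% = 100 * sd / mean with the sample (n - 1) standard deviation.  Used
#' as the QC repeatability statistic: features whose pooled-QC injections
#' have RSD% at or above a threshold (20% by default) are considered
#' irreproducible and removed.
#'
#' @param values numeric vector, length >= 2.
#' @return RSD in percent.  If the mean is zero or negative the RSD is
#'   undefined and `Inf` is returned with attribute `flag = "nonpositive_mean"`.
#' @export
#' @examples
#' rsd_percent(c(80, 100, 120))  # 20
rsd_percent <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("rsd_percent() needs a numeric vector of length >= 2", call. = FALSE)
  m <- mean(values)
  if (m <= 0) {
    out <- Inf
    attr(out, "flag") <- "nonpositive_mean"
    return(out)
  }
  100 * stats::sd(values) / m
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, ~0 for
#' independent ones.  Used to score recovery of planted sample groupings by
#' hierarchical clustering.
#'
#' @param a,b integer/character vectors of cluster labels, same length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)  # degenerate: both partitions trivial
  (nij - expected) / (mx - expected)
}

## internal: stop with a labelled validation error
.fail <- function(...) stop(sprintf(...), call. = FALSE)

## internal: delimiter sniffing for peak-table/metadata files (comma vs tab)
.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) .fail("file '%s' is empty", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

## internal: maximum-likelihood gamma fit (location fixed at 0).
## Newton iteration on the shape profile: log(k) - digamma(k) = s,
## s = log(mean(x)) - mean(log(x)); rate = shape / mean(x).
fit_gamma_ml <- function(x, max_iter = 50L, tol = 1e-10) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 2L) .fail("gamma fit needs >= 2 positive values")
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) .fail("gamma fit degenerate (all values equal)")
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < tol * k) { k <- k_new; break }
    k <- k_new
  }
  list(shape = k, rate = k / mean(x))
}
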