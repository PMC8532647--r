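## Feature-FTOE correlation screening and multivariate structure:
## per-feature Pearson r over pooled study samples, the strict
## |r| > 0.5 & p < 0.05 significance rule, per-feature autoscaling, PCA by
## SVD with a deterministic sign convention, and Ward/Euclidean
## hierarchical clustering of samples.

#' Pair study injections with FTOE values
#'
#' Each study injection uses the FTOE measured for its own patient and
#' timepoint.  When oximetry is missing at a timepoint the nearest earlier
#' measurement of the same patient is carried forward and flagged.
#'
#' @param ft a `feature_table`.
#' @param clinical clinical sheet with `patient_id`, `timepoint` and either
#'   an `ftoe` column or `sao2`/`sco2` to derive it from.
#' @return data.frame (one row per study injection): `injection_id`,
#'   `patient_id`, `timepoint`, `ftoe`, `carried_forward`.
#' @export
match_ftoe <- function(ft, clinical) {
  if (!"ftoe" %in% names(clinical)) clinical <- derive_oximetry(clinical)
  st <- study_idx(ft)
  inj <- ft$injections[st, ]
  tp_rank <- match(inj$timepoint, TIMEPOINT_LEVELS)
  cl_rank <- match(clinical$timepoint, TIMEPOINT_LEVELS)
  ftoe <- rep(NA_real_, nrow(inj)); carried <- logical(nrow(inj))
  for (i in seq_len(nrow(inj))) {
    rows <- which(clinical$patient_id == inj$patient_id[i] &
                    !is.na(clinical$ftoe))
    if (!length(rows)) next
    exact <- rows[clinical$timepoint[rows] == inj$timepoint[i]]
    if (length(exact)) {
      ftoe[i] <- clinical$ftoe[exact[1]]
    } else {
      earlier <- rows[cl_rank[rows] <= tp_rank[i]]
      if (length(earlier)) {
        ftoe[i] <- clinical$ftoe[earlier[which.max(cl_rank[earlier])]]
        carried[i] <- TRUE
      }
    }
  }
  if (anyNA(ftoe))
    .fail("no FTOE available for study injection(s): %s",
          paste(inj$injection_id[is.na(ftoe)], collapse = ", "))
  data.frame(injection_id = inj$injection_id, patient_id = inj$patient_id,
             timepoint = inj$timepoint, ftoe = ftoe,
             carried_forward = carried)
}

#' Pearson correlation of every feature with FTOE
#'
#' Samples are pooled across patients and timepoints (replicating the
#' published screening; repeated measures are ignored).  Two-sided p-values
#' come from the t distribution with n - 2 degrees of freedom.  Features
#' with zero variance get NA r/p and flag `"constant"`.
#'
#' @param ft a `feature_table` (study injections are used).
#' @param ftoe either the data.frame from [match_ftoe()] or a numeric
#'   vector of FTOE values ordered like the study injections.
#' @param config a [pipeline_config()]; supplies the significance rule.
#' @return data.frame: feature_id, mz, rt, mode, r, p, n, class
#'   (`positive` / `negative` / `nonsignificant`), flag.
#' @export
pearson_with_ftoe <- function(ft, ftoe, config = pipeline_config()) {
  st <- study_idx(ft)
  if (is.data.frame(ftoe)) {
    m <- match(ft$injections$injection_id[st], ftoe$injection_id)
    if (anyNA(m))
      .fail("study injections without FTOE pairing: %s",
            paste(ft$injections$injection_id[st][is.na(m)], collapse = ", "))
    f <- ftoe$ftoe[m]
  } else f <- as.numeric(ftoe)
  n <- length(st)
  if (length(f) != n) .fail("FTOE vector length %d != %d study samples",
                            length(f), n)
  if (n < 3L) .fail("need >= 3 study samples")
  x <- ft$intensities[, st, drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  r <- rep(NA_real_, nrow(x))
  ok <- sds > 0 & stats::sd(f) > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(x[ok, , drop = FALSE]), f))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  res <- data.frame(feature_id = ft$features$feature_id,
                    mz = ft$features$mz, rt = ft$features$rt,
                    mode = ft$features$mode, r = r, p = p,
                    n = rep.int(n, nrow(ft$features)),
                    flag = ifelse(ok, NA_character_, "constant"))
  res$class <- classify_significant(res, config)
  res
}

#' Classify screening results
#'
#' Strict inequalities exactly as published: `positive` iff r > threshold
#' and p < alpha; `negative` iff r < -threshold and p < alpha; otherwise
#' `nonsignificant`.
#'
#' @param results data.frame with columns `r` and `p`.
#' @param config a [pipeline_config()].
#' @return character vector of classes.
#' @export
classify_significant <- function(results, config = pipeline_config()) {
  r <- results$r; p <- results$p
  cls <- rep("nonsignificant", length(r))
  sig <- !is.na(r) & !is.na(p) & p < config$corr_p_threshold
  cls[sig & r > config$corr_r_threshold] <- "positive"
  cls[sig & r < -config$corr_r_threshold] <- "negative"
  cls
}

#' Autoscale a feature matrix
#'
#' Per feature (row): subtract the mean, divide by the sample standard
#' deviation.  Zero-variance rows become all zeros and are flagged in
#' attribute `constant_rows`.
#'
#' @param x numeric matrix, features x samples (>= 2 samples).
#' @return autoscaled matrix.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) .fail("autoscale needs >= 2 samples")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  const <- sdv == 0
  sdv[const] <- 1
  out <- (x - mu) / sdv
  out[const, ] <- 0
  if (any(const)) attr(out, "constant_rows") <- which(const)
  out
}

#' PCA scores of autoscaled data
#'
#' Singular value decomposition of the samples x features matrix (input is
#' features x samples, already autoscaled so each feature has mean 0).
#' Deterministic sign convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x autoscaled matrix, features x samples.
#' @param n_components number of components to keep.
#' @return list with `scores` (samples x components), `explained_variance`
#'   (fractions, nonincreasing) and `loadings`.
#' @export
pca_scores <- function(x, n_components = 2L) {
  z <- t(as.matrix(x))                    # samples x features, columns centered
  sv <- svd(z)
  pos <- sv$d > max(sv$d) * 1e-12
  rank <- sum(pos)
  if (n_components > rank) {
    warning(sprintf("n_components = %d exceeds rank %d; truncated",
                    n_components, rank))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  for (k in keep) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, explained_variance = ev[keep], loadings = loadings)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample profiles with Euclidean distance
#' and Ward's variance-minimizing linkage (`stats::hclust`, method
#' `"ward.D2"`), plus the k-cluster cut.
#'
#' @param x autoscaled matrix, features x samples.
#' @param k number of clusters for the cut (>= 1).
#' @return list with `labels` (k-cut, named by sample), `tree` (the
#'   `hclust` object: `merge`, `height`, `order`).
#' @export
ward_cluster <- function(x, k = 2L) {
  if (k < 1L) .fail("k must be >= 1")
  z <- t(as.matrix(x))
  if (nrow(z) < k) .fail("need >= k samples")
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  names(labels) <- colnames(x)
  list(labels = labels, tree = tree)
}
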