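# Pearson screening, significance rule, autoscaling, PCA, Ward clustering

test_that("exact linear relations give r = +/-1", {
  ft <- toy_table(n_feat = 2, n_study = 6, seed = 1)
  st <- which(ft$injections$role == "study")
  f <- seq(0.2, 0.45, length.out = 6)
  ft$intensities[1, st] <- 2 * f + 1
  ft$intensities[2, st] <- 1 - f
  res <- pearson_with_ftoe(ft, f)
  expect_equal(res$r, c(1, -1), tolerance = 1e-12)
  # streaming cor equals the naive two-pass definition
  x <- ft$intensities[1, st]
  naive <- sum((x - mean(x)) * (f - mean(f))) /
    sqrt(sum((x - mean(x))^2) * sum((f - mean(f))^2))
  expect_equal(res$r[1], naive, tolerance = 1e-12)
})

test_that("constant features are flagged, unmatched samples error", {
  ft <- toy_table(n_feat = 1, n_study = 5, seed = 2)
  st <- which(ft$injections$role == "study")
  ft$intensities[1, st] <- 7
  res <- pearson_with_ftoe(ft, runif(5, 0.2, 0.4))
  expect_identical(res$flag, "constant")
  expect_true(is.na(res$r))
  expect_error(pearson_with_ftoe(ft, 1:3), "study samples")
})

test_that("significance rule uses strict boundaries and is monotone", {
  cfg <- pipeline_config()
  res <- data.frame(r = c(0.51, 0.50, -0.9, -0.51, 0.9),
                    p = c(0.04, 0.01, 0.2, 0.049, 0.05))
  expect_equal(classify_significant(res, cfg),
               c("positive", "nonsignificant", "nonsignificant",
                 "negative", "nonsignificant"))
  # monotonicity: decreasing p / increasing |r| never de-significs
  set.seed(4)
  for (i in 1:50) {
    r <- runif(1, -1, 1); p <- runif(1)
    a <- classify_significant(data.frame(r = r, p = p), cfg)
    b <- classify_significant(data.frame(r = sign(r) * min(1, abs(r) + 0.2),
                                         p = p / 2), cfg)
    if (a != "nonsignificant") expect_identical(b, a)
  }
})

test_that("autoscale standardizes rows and flags constants", {
  expect_equal(autoscale(matrix(c(1, 2, 3), 1))[1, ], c(-1, 0, 1))
  x <- rbind(runif(10), rep(5, 10))
  z <- autoscale(x)
  expect_equal(attr(z, "constant_rows"), 2L)
  expect_equal(z[2, ], rep(0, 10))
  set.seed(5)
  m <- matrix(rnorm(200), 10)
  z <- autoscale(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 10))
})

test_that("PCA: rank-1 variance, sign convention, equivariance, recon", {
  set.seed(66)
  w <- rnorm(8); w <- w - mean(w)     # centered sample scores
  x <- outer(runif(6), w)             # rank-1, rows mean-centered
  p <- pca_scores(x, 1)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-10)

  set.seed(6)
  z <- autoscale(matrix(rnorm(120), 8))
  p2 <- pca_scores(z, 2)
  # largest-magnitude loading positive
  for (k in 1:2)
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, k])), k], 0)
  # permutation equivariance over samples
  perm <- sample(ncol(z))
  p3 <- pca_scores(z[, perm], 2)
  expect_equal(p3$scores, p2$scores[perm, ], tolerance = 1e-8)
  # full reconstruction with all components
  pf <- pca_scores(z, min(dim(z)))
  rec <- pf$scores %*% t(pf$loadings)
  expect_lt(max(abs(t(z) - rec)) / max(abs(z)), 1e-8)
  expect_warning(pca_scores(z, 50), "truncated")
})

test_that("PCA recovers a planted one-dimensional gradient", {
  set.seed(7)
  grad <- rep(1:7, each = 9)                 # timepoint index per sample
  x <- outer(rnorm(40), grad) + matrix(rnorm(40 * 63, sd = 2), 40)
  p <- pca_scores(autoscale(x), 2)
  rho <- spearman_assoc(p$scores[, 1], grad)$rho
  expect_gt(abs(rho), 0.8)
})

test_that("Ward/Euclidean separates obvious groups deterministically", {
  x <- matrix(c(0, 0.1, 0.2, 10, 10.1), 1)   # 1 feature, 5 samples
  colnames(x) <- paste0("s", 1:5)
  cl <- ward_cluster(x, 2)
  expect_equal(unname(cl$labels[1:3]), rep(cl$labels[[1]], 3))
  expect_equal(unname(cl$labels[4:5]), rep(cl$labels[[4]], 2))
  expect_false(cl$labels[[1]] == cl$labels[[4]])
  # merge heights nondecreasing
  expect_true(all(diff(cl$tree$height) >= -1e-12))
  expect_error(ward_cluster(x, 0), "k must be")
})

test_that("FTOE pairing carries forward missing timepoints with a flag", {
  ft <- toy_table(n_feat = 2, n_study = 7, seed = 9)
  cl <- toy_clinical()
  cl <- cl[cl$timepoint != "72h", ]          # missing oximetry at 72 h
  m <- match_ftoe(ft, cl)
  expect_equal(nrow(m), 7L)
  i72 <- which(m$timepoint == "72h")
  expect_true(m$carried_forward[i72])
  expect_equal(m$ftoe[i72], m$ftoe[m$timepoint == "48h"])
  expect_false(any(m$carried_forward[-i72]))
})
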