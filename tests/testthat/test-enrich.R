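# m/z annotation, top-fraction selection, EASE p, permutation-gamma null

test_that("annotation respects ppm tolerance per mode", {
  lib <- data.frame(pathway_id = "pw1", name = "toy",
                    compound_code = "GLC",
                    neutral_mass = formula_mass("C6H12O6"))  # 180.063388
  feats <- data.frame(feature_id = "f1", mz = 181.0720, mode = "positive")
  hit <- annotate_mz(feats, lib, ppm = 10)   # [M+H]+ 181.070664, 7.4 ppm
  expect_equal(hit$compound_code, "GLC")
  expect_equal(hit$adduct, "[M+H]+")
  expect_equal(hit$ppm_error, (181.0720 - 181.070664) / 181.070664 * 1e6,
               tolerance = 1e-4)
  expect_equal(nrow(annotate_mz(feats, lib, ppm = 5)), 0L)
  # negative-mode feature at the same mass must not match positive adducts
  featn <- data.frame(feature_id = "f2", mz = 181.0720, mode = "negative")
  expect_equal(nrow(annotate_mz(featn, lib, ppm = 10)), 0L)
  expect_equal(nrow(annotate_mz(feats, lib[0, ], ppm = 10)), 0L)
})

test_that("top-fraction selection keeps boundary ties", {
  p <- c(0.001, 0.5, 0.01, 0.9, 0.2, 0.03, 0.6, 0.7, 0.8, 0.95,
         0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.92, 0.99)
  expect_setequal(select_top_fraction(p, 0.10), c(1L, 3L))
  expect_length(select_top_fraction(p, 1.0), 20L)
  ties <- c(0.01, 0.05, 0.05, 0.05, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  expect_setequal(select_top_fraction(ties, 0.20), 1:4)  # all tied included
})

test_that("EASE p matches the worked case and rejects bad counts", {
  expect_equal(pathway_ease_p(0, 5, 6, 20), 1)
  expect_equal(pathway_ease_p(5, 5, 6, 20), 540 / 38760, tolerance = 1e-12)
  expect_error(pathway_ease_p(6, 5, 6, 20), "inconsistent")
})

test_that("EASE p equals choose() enumeration on random small tables", {
  oracle <- function(k, K, n, N) {
    if (k == 0) return(1)
    j <- max(k - 1, max(0, n - (N - K))):min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  set.seed(8)
  for (i in 1:200) {
    N <- sample(1:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(pathway_ease_p(k, K, n, N), oracle(k, K, n, N),
                 tolerance = 1e-12,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
})

test_that("permutation-gamma null is seeded-deterministic and calibrated", {
  set.seed(10)
  lib <- do.call(rbind, lapply(1:4, function(i)
    data.frame(pathway_id = paste0("pw", i), name = paste0("pw", i),
               compound_code = paste0("C", i, "_", 1:5),
               neutral_mass = runif(5, 100, 800))))
  feats <- data.frame(feature_id = paste0("f", 1:60),
                      mz = c(lib$neutral_mass + 1.007276,
                             runif(40, 100, 900)),
                      mode = "positive")
  ann <- annotate_mz(feats, lib, 10)
  obs <- data.frame(pathway_id = paste0("pw", 1:4),
                    raw_p = c(0.001, 0.2, 1, 0.05))
  a <- permutation_gamma_adjust(obs, ann, lib, feats$feature_id, 6,
                                permutations = 200, seed = 3)
  b <- permutation_gamma_adjust(obs, ann, lib, feats$feature_id, 6,
                                permutations = 200, seed = 3)
  expect_identical(a$adj_p, b$adj_p)
  expect_true(all(a$adj_p >= 0 & a$adj_p <= 1))
  expect_equal(a$adj_p[3], 1)            # raw p = 1 stays 1
  expect_lt(a$adj_p[1], a$adj_p[2])      # monotone in raw p
})

test_that("enrich recovers a planted pathway and handles edge cases", {
  p <- simulation_params(n_features_per_mode = 150, rng_seed = 4)
  sim <- simulate_batch(simulate_cohort(p), p, "positive")
  st <- which(sim$table$injections$role == "study")
  f <- sim$truth$ftoe$ftoe[match(sim$table$injections$injection_id[st],
                                 sim$truth$ftoe$injection_id)]
  res <- pearson_with_ftoe(sim$table, f)
  cfg <- pipeline_config(rng_seed = 4)
  enr <- enrich(res, default_pathway_library(), cfg)
  expect_equal(enr$pathway_id[1], "map00030")
  expect_lt(enr$adj_p[1], 0.05)
  # row order invariance of the full result
  res2 <- res[sample(nrow(res)), ]
  enr2 <- enrich(res2, default_pathway_library(), cfg)
  expect_equal(enr2$adj_p, enr$adj_p, tolerance = 1e-12)
  expect_equal(enr2$pathway_id, enr$pathway_id)
  # nothing significant -> all raw p = 1
  res3 <- res; res3$p <- NULL; res3$p <- rep(1, nrow(res))
  enr3 <- enrich(res3, default_pathway_library(), cfg)
  expect_true(all(enr3$n_hits >= enr3$n_sig_hits))
  # no annotations -> warning and empty result
  res4 <- res; res4$mz <- res4$mz + 3
  expect_warning(enr4 <- enrich(res4, default_pathway_library(), cfg),
                 "no feature annotated")
  expect_equal(nrow(enr4), 0L)
})

test_that("n_sig_hits is monotone in the significant-set size", {
  p <- simulation_params(n_features_per_mode = 100, rng_seed = 9)
  sim <- simulate_batch(simulate_cohort(p), p, "positive")
  st <- which(sim$table$injections$role == "study")
  f <- sim$truth$ftoe$ftoe[match(sim$table$injections$injection_id[st],
                                 sim$truth$ftoe$injection_id)]
  res <- pearson_with_ftoe(sim$table, f)
  lib <- default_pathway_library()
  prev <- 0L
  for (frac in c(0.05, 0.1, 0.3, 1.0)) {
    cfg <- pipeline_config(sig_top_fraction = frac, rng_seed = 1)
    e <- enrich(res, lib, cfg)
    tot <- sum(e$n_sig_hits)
    expect_gte(tot, prev)
    prev <- tot
  }
})
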