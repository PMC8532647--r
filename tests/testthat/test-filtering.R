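# blank / RSD / drug-ion exclusion rules

test_that("rsd_percent matches hand arithmetic and a two-pass oracle", {
  expect_equal(rsd_percent(c(100, 100, 100)), 0)
  expect_equal(rsd_percent(c(80, 100, 120)), 20.0)
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(2:30, 1), 1, 1e6)
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(rsd_percent(v), 100 * s / m, tolerance = 1e-10)
  }
  expect_identical(as.numeric(rsd_percent(c(-5, 5))), Inf)
  expect_error(rsd_percent(5), "length >= 2")
})

test_that("blank rule boundaries: strict <5x, zero blanks always kept", {
  make <- function(blank, study) {
    toy_table(n_feat = 1, n_study = 5, n_blank = 1, seed = 1,
              intensities = matrix(c(100, 100, 100, 100, 100, 100,
                                     rep(study, 5), blank), 1))
  }
  expect_equal(blank_filter(make(10, 49), 5)$removed, "F001")
  expect_length(blank_filter(make(10, 50), 5)$removed, 0)   # strict <
  expect_length(blank_filter(make(0, 1), 5)$removed, 0)     # zero blank
  noblank <- toy_table(n_blank = 0, seed = 2)
  expect_error(blank_filter(noblank), "blank injection")
})

test_that("rsd rule is inclusive at the threshold", {
  make_qc <- function(qc) {
    toy_table(n_feat = 1, n_qc = 3, n_study = 3, seed = 1,
              intensities = matrix(c(1, 1, qc, 100, 100, 100, 1), 1))
  }
  expect_equal(rsd_filter(make_qc(c(80, 100, 120)), 20)$removed, "F001")
  expect_length(rsd_filter(make_qc(c(99, 100, 101)), 20)$removed, 0)
  expect_length(rsd_filter(make_qc(c(80, 100, 120)), Inf)$removed, 0)
})

test_that("drug ion expansion matches the element-mass oracle", {
  caffeine <- list(name = "caffeine", neutral_mass = formula_mass("C8H10N4O2"))
  expect_equal(caffeine$neutral_mass, 194.080376, tolerance = 1e-6)
  pos <- expand_drug_ions(caffeine, "positive")
  expect_equal(pos$mz[pos$label == "caffeine [M+H]+"], 195.087652,
               tolerance = 1e-6)
  expect_equal(pos$mz[pos$label == "caffeine [M+Na]+"], 217.069594,
               tolerance = 1e-6)
  # isotopologue spacing is 1.003355 above each parent ion
  for (lab in c("[M+H]+", "[M+Na]+", "[M+K]+"))
    expect_equal(pos$mz[pos$label == paste("caffeine", lab, "13C")],
                 pos$mz[pos$label == paste("caffeine", lab)] + 1.003355)
  neg <- expand_drug_ions(caffeine, "negative")
  expect_equal(neg$mz[neg$label == "caffeine [M-H]-"],
               194.080376 - 1.007276, tolerance = 1e-6)
})

test_that("drug filter removes by m/z delta with strict tolerance", {
  drugs <- data.frame(name = "caffeine",
                      neutral_mass = formula_mass("C8H10N4O2"))
  make <- function(mz) {
    ft <- toy_table(n_feat = 1, seed = 1)
    ft$features$mz <- mz
    ft
  }
  expect_equal(drug_filter(make(195.0850), drugs, 0.010)$removed, "F001")
  expect_length(drug_filter(make(195.0990), drugs, 0.010)$removed, 0)
  expect_length(drug_filter(make(195.087652), drugs, 0)$removed, 0)
  expect_warning(out <- drug_filter(make(195.0850), drugs[0, ], 0.010),
                 "no-op")
  expect_length(out$removed, 0)
})

test_that("cascade equals brute force, is idempotent, counts reconcile", {
  drugs <- default_drug_list()
  for (seed in c(3, 14)) {
    p <- simulation_params(n_features_per_mode = 50, rng_seed = seed)
    sim <- simulate_batch(simulate_cohort(p), p, "positive", drugs = drugs)
    fc <- apply_filter_cascade(sim$table, drugs)
    expect_setequal(fc$table$features$feature_id,
                    brute_force_survivors(sim$table, drugs))
    r <- fc$report
    expect_equal(r$n_input, r$n_surviving + r$n_removed_blank +
                   r$n_removed_rsd + r$n_removed_drug)
    expect_false(anyDuplicated(r$reasons$feature_id) > 0)
    # idempotence
    fc2 <- apply_filter_cascade(fc$table, drugs)
    expect_identical(fc2$table$features$feature_id,
                     fc$table$features$feature_id)
    expect_equal(fc2$report$n_surviving, fc$report$n_surviving)
  }
})

test_that("survivors are independent of rule order", {
  drugs <- default_drug_list()
  p <- simulation_params(n_features_per_mode = 50, rng_seed = 21)
  sim <- simulate_batch(simulate_cohort(p), p, "negative", drugs = drugs)
  cfg <- pipeline_config()
  a <- apply_filter_cascade(sim$table, drugs, cfg)$table$features$feature_id
  # drug -> rsd -> blank
  d <- drug_filter(sim$table, drugs, cfg$drug_mz_tolerance)$table
  r <- rsd_filter(d, cfg$rsd_threshold_percent)$table
  b <- blank_filter(r, cfg$blank_ratio)$table
  expect_setequal(a, b$features$feature_id)
})

test_that("planted contaminant recovery at defaults", {
  drugs <- default_drug_list()
  removed_frac <- function(sim, cls) {
    fc <- apply_filter_cascade(sim$table, drugs)
    tr <- sim$truth$features
    ids <- tr$feature_id[tr$class == cls]
    mean(!ids %in% fc$table$features$feature_id)
  }
  for (seed in 0:2) {
    p <- simulation_params(n_features_per_mode = 120, rng_seed = seed)
    sim <- simulate_batch(simulate_cohort(p), p, "positive", drugs = drugs)
    expect_gte(removed_frac(sim, "blank_contaminant"), 0.95)
    expect_gte(removed_frac(sim, "drug_ion"), 0.95)
    expect_lte(removed_frac(sim, "stable"), 0.10)
  }
})
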