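# synthetic cohort and batch generator

test_that("params validation enforces the stated invariants", {
  expect_error(simulation_params(frac_drifting = 0.9,
                                 frac_ftoe_correlated = 0.2), "sum")
  expect_error(simulation_params(n_patients = 1), "n_patients")
  expect_error(simulation_params(qc_period = 1), "qc_period")
})

test_that("cohort hits the anchors with zero noise and 63 rows", {
  p <- simulation_params(patient_sd = 0, measurement_sd = 0)
  co <- simulate_cohort(p)
  expect_equal(nrow(co), 63L)
  expect_equal(unique(co$sao2[co$timepoint == "pre"]), 0.856)
  expect_equal(unique(co$sco2[co$timepoint == "pre"]), 0.500)
  # FTOE decreases after 6 h
  med <- tapply(co$ftoe, co$timepoint, median)
  expect_gt(med[["6h"]], med[["24h"]])
  expect_gt(med[["pre"]], med[["6h"]])
})

test_that("flat anchors give constant FTOE", {
  p <- simulation_params(patient_sd = 0, measurement_sd = 0,
                         sao2_anchors = rep(0.9, 7),
                         rcso2_anchors = rep(0.6, 7))
  co <- simulate_cohort(p)
  expect_equal(var(co$ftoe), 0)
})

test_that("injection sequence follows the QC grammar", {
  p <- simulation_params(n_features_per_mode = 5, rng_seed = 3)
  sim <- simulate_batch(simulate_cohort(p), p, "positive")
  inj <- sim$table$injections
  expect_equal(sum(inj$role == "study"), 63L)
  expect_equal(sum(inj$role == "conditioning"), 8L)
  expect_equal(sum(inj$role == "blank"), 2L)
  # first QC right after conditioning
  expect_equal(min(inj$order[inj$role == "qc"]), p$n_conditioning + 1)
  # exactly qc_period study samples between consecutive QCs (last gap free)
  qc_orders <- sort(inj$order[inj$role == "qc"])
  gaps <- vapply(seq_len(length(qc_orders) - 1), function(i)
    sum(inj$role == "study" & inj$order > qc_orders[i] &
          inj$order < qc_orders[i + 1]), integer(1))
  expect_true(all(gaps[-length(gaps)] == p$qc_period))
  expect_lte(gaps[length(gaps)], p$qc_period)
  # last non-blank injection is a QC
  nb <- inj[inj$role != "blank", ]
  expect_equal(nb$role[which.max(nb$order)], "qc")
})

test_that("truth labels partition features with exact rounded counts", {
  p <- simulation_params(n_features_per_mode = 137, rng_seed = 5)
  sim <- simulate_batch(simulate_cohort(p), p, "negative")
  tab <- table(sim$truth$features$class)
  expect_equal(sum(tab), 137L)
  expect_equal(unname(tab[["drifting"]]), round(0.3 * 137))
  expect_equal(unname(tab[["blank_contaminant"]]), round(0.05 * 137))
  expect_equal(unname(tab[["drug_ion"]]), round(0.03 * 137))
  expect_equal(unname(tab[["ftoe_correlated"]]), round(0.1 * 137))
  # planted pathway's compounds are exactly those assigned to correlated
  tr <- sim$truth$features
  lib <- default_pathway_library()
  planted <- unique(lib$compound_code[lib$pathway_id == "map00030"])
  expect_setequal(unique(na.omit(tr$compound_code)), planted)
})

test_that("same seed reproduces table and truth; noiseless QCs have RSD 0", {
  p <- simulation_params(n_features_per_mode = 20, rng_seed = 12)
  a <- simulate_batch(simulate_cohort(p), p, "positive")
  b <- simulate_batch(simulate_cohort(p), p, "positive")
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$truth$features, b$truth$features)

  p0 <- simulation_params(n_features_per_mode = 10, drift_amplitude = 0,
                          noise_cv = 0, rng_seed = 1)
  sim <- simulate_batch(simulate_cohort(p0), p0, "positive")
  qc <- which(sim$table$injections$role == "qc")
  rsds <- apply(sim$table$intensities[, qc], 1, rsd_percent)
  expect_equal(unname(rsds), rep(0, 10))
})

test_that("planted correlations land near the target at n = 63", {
  # Fisher-z bound: at n=63, sampling sd of z is ~0.129, so |r - 0.7| is
  # within 0.15 for ~97% of features; require >= 90% over a few seeds
  hits <- 0L; total <- 0L
  for (seed in 0:4) {
    p <- simulation_params(n_features_per_mode = 100, rng_seed = seed)
    sim <- simulate_batch(simulate_cohort(p), p, "positive")
    st <- which(sim$table$injections$role == "study")
    f <- sim$truth$ftoe$ftoe[match(sim$table$injections$injection_id[st],
                                   sim$truth$ftoe$injection_id)]
    idx <- which(sim$truth$features$class == "ftoe_correlated")
    r <- as.numeric(cor(t(log(sim$table$intensities[idx, st])), f))
    hits <- hits + sum(abs(abs(r) - p$target_abs_r) <= 0.15)
    total <- total + length(idx)
  }
  expect_gte(hits / total, 0.90)
})

test_that("write_simulation emits re-readable pipeline inputs", {
  dir <- withr::local_tempdir()
  p <- simulation_params(n_features_per_mode = 12, rng_seed = 2)
  sim <- simulate_study(p)
  write_simulation(sim, dir)
  back <- read_feature_table(file.path(dir, "peaktable_pos.csv"),
                             file.path(dir, "metadata_pos.tsv"))
  expect_equal(back$intensities, sim$pos$table$intensities,
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "truth.json")))
  lib <- read_pathway_library(file.path(dir, "pathway_library.tsv"))
  expect_setequal(unique(lib$pathway_id),
                  c("map00030", "map00040", "map00053", "map00562"))
})
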