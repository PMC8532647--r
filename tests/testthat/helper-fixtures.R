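# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# Small deterministic peak table: n_feat features, a batch with
# conditioning/QC/study/blank injections.
toy_table <- function(n_feat = 3, n_study = 4, n_qc = 4, n_blank = 1,
                      n_cond = 2, mode = "positive", seed = NULL,
                      intensities = NULL) {
  if (!is.null(seed)) set.seed(seed)
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n_feat)),
    mz = seq(100, 900, length.out = n_feat),
    rt = seq(30, 300, length.out = n_feat),
    mode = mode)
  n_inj <- n_cond + n_qc + n_study + n_blank
  role <- c(rep("conditioning", n_cond), rep("qc", n_qc),
            rep("study", n_study), rep("blank", n_blank))
  if (n_study > 7) stop("toy_table supports at most 7 study samples")
  tps <- c("pre", "5min", "6h", "24h", "48h", "72h", "96h")[seq_len(n_study)]
  injections <- data.frame(
    injection_id = paste0("I", seq_len(n_inj)),
    order = seq_len(n_inj), role = role,
    patient_id = NA_character_, timepoint = NA_character_)
  st <- which(role == "study")
  injections$patient_id[st] <- "P1"     # unique patient+timepoint pairs
  injections$timepoint[st] <- tps
  if (is.null(intensities))
    intensities <- matrix(stats::runif(n_feat * n_inj, 50, 150),
                          n_feat, n_inj)
  feature_table(features, injections, intensities)
}

# Randomized table for round-trip property tests.
random_table <- function(seed) {
  set.seed(seed)
  n_feat <- sample(1:8, 1)
  n_study <- sample(2:6, 1)
  toy_table(n_feat = n_feat, n_study = n_study,
            mode = sample(c("positive", "negative"), 1),
            intensities = matrix(
              stats::rexp(n_feat * (2 + 4 + n_study + 1), rate = 1e-4),
              n_feat))
}

# Independent brute-force filter oracle used by cascade tests: applies the
# three published rules feature-by-feature with naive arithmetic.
brute_force_survivors <- function(ft, drugs, ratio = 5, rsd_thr = 20,
                                  tol = 0.010) {
  inj <- ft$injections
  keep <- character()
  for (f in seq_len(nrow(ft$features))) {
    x <- ft$intensities[f, ]
    blank <- max(x[inj$role == "blank"])
    med <- stats::median(x[inj$role == "study"])
    if (blank > 0 && med < ratio * blank) next
    qc <- x[inj$role == "qc"]
    m <- mean(qc)
    s <- sqrt(sum((qc - m)^2) / (length(qc) - 1))
    if (m <= 0 || 100 * s / m >= rsd_thr) next
    hit <- FALSE
    for (d in seq_len(nrow(drugs))) {
      ions <- adduct_mz(drugs$neutral_mass[d], ft$features$mode[f],
                        isotopologues = TRUE)
      if (any(abs(ft$features$mz[f] - ions) < tol)) { hit <- TRUE; break }
    }
    if (hit) next
    keep <- c(keep, ft$features$feature_id[f])
  }
  keep
}

# A small clinical sheet matching toy_table's single patient.
toy_clinical <- function() {
  data.frame(patient_id = "P1",
             timepoint = c("pre", "5min", "6h", "24h", "48h", "72h", "96h"),
             sao2 = c(0.856, 0.860, 0.891, 0.900, 0.900, 0.900, 0.900),
             sco2 = c(0.500, 0.528, 0.630, 0.692, 0.692, 0.692, 0.692))
}

# iterative lexicographic permutation generator (oracle-side only)
gtools_permutations <- function(n) {
  out <- matrix(0L, factorial(n), n)
  p <- seq_len(n)
  for (i in seq_len(nrow(out))) {
    out[i, ] <- p
    # next lexicographic permutation
    k <- max(which(p[-n] < p[-1]), -Inf)
    if (!is.finite(k)) break
    l <- max(which(p > p[k]))
    tmp <- p[k]; p[k] <- p[l]; p[l] <- tmp
    p[(k + 1):n] <- rev(p[(k + 1):n])
  }
  out
}

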