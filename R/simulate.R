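## Synthetic cohort + LC-MS batch generator.
##
## Emulates the study design the pipeline targets: 9 infants sampled at 7
## timepoints (5 min pre-procedure; 5 min, 6, 24, 48, 72, 96 h post), one
## analytical batch per ionization mode opened by 8 conditioning QC
## injections, a pooled QC after every 6th study sample plus batch start
## and end, and 2 blank injections (one mid-batch, one at the end).
## Intensities are baseline x smooth injection-order drift x multiplicative
## log-normal noise, with planted feature classes (drifting, blank
## contaminant, drug ion, FTOE-correlated) recorded in a truth registry so
## every downstream stage can be scored against ground truth.

#' Simulation parameters
#'
#' Defaults state the emulated study design: cohort size, batch layout and
#' the planted-structure fractions.  Clinical trajectories are anchored to
#' the published medians (SaO2 0.856 pre rising to 0.900 by 24 h; rcSO2
#' 0.50 pre, 0.528 at 5 min, 0.63 at 6 h, 0.692 at 24 h, plateau after),
#' linearly interpolated in time between printed values, so FTOE falls
#' after 6 h.
#'
#' @param n_patients number of patients (>= 2).
#' @param timepoints sampling timepoint labels.
#' @param n_features_per_mode features per ionization mode.
#' @param frac_drifting,frac_blank_contaminant,frac_drug,frac_ftoe_correlated
#'   planted class fractions (must sum to <= 1; remainder is `stable`).
#' @param target_abs_r population |Pearson r| of planted correlated
#'   features with FTOE.
#' @param noise_cv multiplicative log-normal intensity noise CV.
#' @param drift_amplitude relative amplitude of each drift component
#'   (a linear trend and one low-frequency cosine).
#' @param qc_period study samples between consecutive QCs.
#' @param n_conditioning conditioning QC injections opening the batch.
#' @param n_blanks analytical blank injections.
#' @param sao2_anchors,rcso2_anchors per-timepoint median saturations
#'   (fractions).
#' @param patient_sd,measurement_sd cohort noise: patient-level random
#'   effect on rcSO2 and per-measurement noise on both saturations.
#' @param rng_seed integer seed; everything downstream is a pure function
#'   of it.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_patients = 9L,
                              timepoints = TIMEPOINT_LEVELS,
                              n_features_per_mode = 500L,
                              frac_drifting = 0.3,
                              frac_blank_contaminant = 0.05,
                              frac_drug = 0.03,
                              frac_ftoe_correlated = 0.1,
                              target_abs_r = 0.7,
                              noise_cv = 0.08,
                              drift_amplitude = 0.3,
                              qc_period = 6L,
                              n_conditioning = 8L,
                              n_blanks = 2L,
                              sao2_anchors = c(0.856, 0.860, 0.891, 0.900,
                                               0.900, 0.900, 0.900),
                              rcso2_anchors = c(0.500, 0.528, 0.630, 0.692,
                                                0.692, 0.692, 0.692),
                              patient_sd = 0.03,
                              measurement_sd = 0.015,
                              rng_seed = 1L) {
  p <- list(n_patients = as.integer(n_patients), timepoints = timepoints,
            n_features_per_mode = as.integer(n_features_per_mode),
            frac_drifting = frac_drifting,
            frac_blank_contaminant = frac_blank_contaminant,
            frac_drug = frac_drug,
            frac_ftoe_correlated = frac_ftoe_correlated,
            target_abs_r = target_abs_r, noise_cv = noise_cv,
            drift_amplitude = drift_amplitude,
            qc_period = as.integer(qc_period),
            n_conditioning = as.integer(n_conditioning),
            n_blanks = as.integer(n_blanks),
            sao2_anchors = sao2_anchors, rcso2_anchors = rcso2_anchors,
            patient_sd = patient_sd, measurement_sd = measurement_sd,
            rng_seed = as.integer(rng_seed))
  fr <- p$frac_drifting + p$frac_blank_contaminant + p$frac_drug +
    p$frac_ftoe_correlated
  if (fr > 1) .fail("planted class fractions sum to %.2f > 1", fr)
  if (p$n_patients < 2L) .fail("n_patients must be >= 2")
  if (p$qc_period < 2L) .fail("qc_period must be >= 2")
  if (length(p$sao2_anchors) != length(p$timepoints) ||
      length(p$rcso2_anchors) != length(p$timepoints))
    .fail("anchor vectors must match the number of timepoints")
  structure(p, class = "simulation_params")
}

#' Simulate the cohort oximetry table
#'
#' Per patient and timepoint, SaO2 and rcSO2 are drawn around the anchored
#' medians with a patient-level random effect (on rcSO2) and measurement
#' noise on both, clipped to (0, 1]; CEO2 and FTOE are derived.
#'
#' @param params a [simulation_params()].
#' @return data.frame: patient_id, timepoint, sao2, sco2, ceo2, ftoe,
#'   ceo2_negative.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  set.seed(params$rng_seed)
  tp <- params$timepoints
  grid <- expand.grid(timepoint = tp,
                      patient_id = sprintf("P%02d", seq_len(params$n_patients)),
                      stringsAsFactors = FALSE)[, c("patient_id", "timepoint")]
  pat_eff <- stats::rnorm(params$n_patients, 0, params$patient_sd)
  names(pat_eff) <- sprintf("P%02d", seq_len(params$n_patients))
  clip <- function(x) pmin(pmax(x, 0.01), 1)
  i_tp <- match(grid$timepoint, tp)
  grid$sao2 <- clip(params$sao2_anchors[i_tp] +
                      stats::rnorm(nrow(grid), 0, params$measurement_sd))
  grid$sco2 <- clip(params$rcso2_anchors[i_tp] + pat_eff[grid$patient_id] +
                      stats::rnorm(nrow(grid), 0, params$measurement_sd))
  derive_oximetry(grid)
}

## batch injection sequence following the QC grammar:
## conditioning, QC, (qc_period study, QC)..., trailing study, QC;
## blanks: last one at batch end, the rest after interior QCs.
.injection_sequence <- function(params, study_ids) {
  n_study <- length(study_ids)
  seqs <- c(rep("COND", params$n_conditioning), "QC")
  left <- n_study
  while (left > 0) {
    take <- min(params$qc_period, left)
    seqs <- c(seqs, rep("STUDY", take), "QC")
    left <- left - take
  }
  n_qc_interior <- sum(seqs == "QC") - 2L
  if (params$n_blanks > 0) {
    n_mid <- params$n_blanks - 1L
    if (n_mid > 0 && n_qc_interior > 0) {
      qc_pos <- which(seqs == "QC")
      interior <- qc_pos[-c(1L, length(qc_pos))]
      at <- interior[round(seq_len(n_mid) * (length(interior) + 1) /
                             (n_mid + 1))]
      for (a in sort(at, decreasing = TRUE))
        seqs <- append(seqs, "BLANK", after = a)
    }
    seqs <- c(seqs, "BLANK")
  }
  roles <- c(COND = "conditioning", QC = "qc", STUDY = "study",
             BLANK = "blank")[seqs]
  inj <- data.frame(injection_id = NA_character_,
                    order = seq_along(seqs), role = unname(roles),
                    patient_id = NA_character_, timepoint = NA_character_,
                    stringsAsFactors = FALSE)
  inj$injection_id <- paste0(toupper(substr(inj$role, 1, 1)),
                             ave(inj$order, inj$role, FUN = seq_along))
  st <- inj$role == "study"
  inj$injection_id[st] <- study_ids
  inj
}

#' Simulate one LC-MS batch with known planted structure
#'
#' Study samples are injected in randomized order following the QC grammar
#' (see package docs).  Feature classes are planted in exactly the rounded
#' fractions of [simulation_params()]:
#' \itemize{
#'  \item `drifting`: smooth injection-order drift (linear + one
#'    low-frequency cosine, each of relative amplitude `drift_amplitude`);
#'  \item `blank_contaminant`: blank signal on the order of the study
#'    signal, so the `<5x` blank rule removes them;
#'  \item `drug_ion`: m/z placed within 10 mDa of a packaged drug ion;
#'  \item `ftoe_correlated`: a multiplicative FTOE term scaled so the
#'    population Pearson correlation of log-intensity with the sample's
#'    FTOE equals `target_abs_r` (random sign), with m/z placed on adduct
#'    ions of the planted pathway's compounds;
#'  \item `stable`: the remainder (a few of which are placed on decoy
#'    pathway compounds so annotation has a nontrivial universe).
#' }
#'
#' @param cohort output of [simulate_cohort()].
#' @param params a [simulation_params()].
#' @param mode ionization mode of the batch.
#' @param drugs drug list (default: packaged).
#' @param library pathway library (default: packaged).
#' @param planted_pathway pathway id whose compounds carry the correlated
#'   features.
#' @return list with `table` (a `feature_table`) and `truth` (feature
#'   classes, drift/correlation parameters, planted pathway id, per-sample
#'   FTOE).
#' @export
simulate_batch <- function(cohort, params = simulation_params(),
                           mode = c("positive", "negative"),
                           drugs = default_drug_list(),
                           library = default_pathway_library(),
                           planted_pathway = "map00030") {
  mode <- match.arg(mode)
  set.seed(params$rng_seed + if (mode == "positive") 101L else 202L)
  n <- params$n_features_per_mode
  n_drift <- round(params$frac_drifting * n)
  n_blankc <- round(params$frac_blank_contaminant * n)
  n_drug <- round(params$frac_drug * n)
  n_corr <- round(params$frac_ftoe_correlated * n)
  n_stable <- n - n_drift - n_blankc - n_drug - n_corr
  if (n_stable < 0) .fail("class fractions leave no stable features")
  classes <- sample(rep(c("drifting", "blank_contaminant", "drug_ion",
                          "ftoe_correlated", "stable"),
                        c(n_drift, n_blankc, n_drug, n_corr, n_stable)))

  study_ids <- paste0("S_", cohort$patient_id, "_", cohort$timepoint)
  study_ids <- sample(study_ids)  # randomized injection order
  inj <- .injection_sequence(params, study_ids)
  st <- which(inj$role == "study")
  inj$patient_id[st] <- sub("^S_(P[0-9]+)_.*$", "\\1", inj$injection_id[st])
  inj$timepoint[st] <- sub("^S_P[0-9]+_", "", inj$injection_id[st])
  key <- paste(inj$patient_id[st], inj$timepoint[st])
  ftoe <- cohort$ftoe[match(key, paste(cohort$patient_id, cohort$timepoint))]

  prefix <- if (mode == "positive") "FP" else "FN"
  fid <- sprintf("%s%04d", prefix, seq_len(n))
  mz <- round(stats::runif(n, 100, 1000), 4)
  rt <- round(stats::runif(n, 10, 500), 1)

  ## plant drug-ion m/z
  i_drug <- which(classes == "drug_ion")
  if (length(i_drug)) {
    dsel <- sample(nrow(drugs), length(i_drug), replace = TRUE)
    for (j in seq_along(i_drug)) {
      ions <- adduct_mz(drugs$neutral_mass[dsel[j]], mode,
                        isotopologues = TRUE)
      mz[i_drug[j]] <- unname(sample(ions, 1)) + stats::runif(1, -9e-3, 9e-3)
    }
  }
  ## plant correlated features on the planted pathway's compounds
  planted <- unique(library[library$pathway_id == planted_pathway,
                            c("compound_code", "neutral_mass")])
  if (!nrow(planted)) .fail("planted pathway '%s' not in library",
                            planted_pathway)
  i_corr <- which(classes == "ftoe_correlated")
  corr_code <- rep(NA_character_, n)
  if (length(i_corr)) {
    csel <- rep_len(seq_len(nrow(planted)), length(i_corr))
    for (j in seq_along(i_corr)) {
      ions <- adduct_mz(planted$neutral_mass[csel[j]], mode)
      ion <- unname(sample(ions, 1))
      mz[i_corr[j]] <- ion * (1 + stats::runif(1, -5, 5) * 1e-6)
      corr_code[i_corr[j]] <- planted$compound_code[csel[j]]
    }
  }
  ## a handful of stable features on decoy compounds: nontrivial universe
  decoys <- unique(library[library$pathway_id != planted_pathway &
                             !library$compound_code %in% planted$compound_code,
                           c("compound_code", "neutral_mass")])
  i_stable <- which(classes == "stable")
  n_decoy_feat <- min(2L * nrow(decoys), length(i_stable))
  if (n_decoy_feat > 0 && nrow(decoys)) {
    pick <- i_stable[seq_len(n_decoy_feat)]
    dsel <- rep_len(seq_len(nrow(decoys)), n_decoy_feat)
    for (j in seq_along(pick)) {
      ions <- adduct_mz(decoys$neutral_mass[dsel[j]], mode)
      mz[pick[j]] <- unname(sample(ions, 1)) *
        (1 + stats::runif(1, -5, 5) * 1e-6)
    }
  }

  ## intensity model
  baseline <- 10^stats::runif(n, 3, 7)
  sigma <- sqrt(log(1 + params$noise_cv^2))
  n_inj <- nrow(inj)
  t01 <- (inj$order - 1) / max(n_inj - 1, 1)
  drift_sign <- sample(c(-1, 1), n, replace = TRUE)
  drift_freq <- stats::runif(n, 0.5, 1.5)
  drift_phase <- stats::runif(n, 0, 2 * pi)
  is_drift <- classes == "drifting"
  A <- params$drift_amplitude
  drift_mat <- matrix(1, n, n_inj)
  if (any(is_drift) && A > 0) {
    for (f in which(is_drift)) {
      d <- 1 + A * drift_sign[f] * (2 * t01 - 1) +
        A * cos(2 * pi * drift_freq[f] * t01 + drift_phase[f])
      drift_mat[f, ] <- pmax(d, 0.05)
    }
  }
  sd_f <- stats::sd(ftoe)
  beta <- numeric(n)
  corr_sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  if (sd_f > 0 && sigma > 0) {
    r <- params$target_abs_r
    beta[i_corr] <- corr_sign[i_corr] * (r / sqrt(1 - r^2)) * sigma / sd_f
  }
  x <- baseline * drift_mat *
    matrix(exp(stats::rnorm(n * n_inj, 0, sigma)), n, n_inj)
  if (length(i_corr) && sd_f > 0) {
    fc <- ftoe - mean(ftoe)
    x[i_corr, st] <- x[i_corr, st] *
      exp(outer(beta[i_corr], fc))
  }
  bl <- which(inj$role == "blank")
  if (length(bl)) {
    x[, bl] <- 0
    i_bc <- which(classes == "blank_contaminant")
    if (length(i_bc))
      x[i_bc, bl] <- baseline[i_bc] *
        matrix(stats::runif(length(i_bc) * length(bl), 0.5, 2),
               length(i_bc)) * drift_mat[i_bc, bl, drop = FALSE] *
        matrix(exp(stats::rnorm(length(i_bc) * length(bl), 0, sigma)),
               length(i_bc))
  }

  features <- data.frame(feature_id = fid, mz = mz, rt = rt, mode = mode)
  truth <- list(
    features = data.frame(
      feature_id = fid, class = classes, baseline = baseline,
      drift_sign = ifelse(is_drift, drift_sign, NA_real_),
      drift_freq = ifelse(is_drift, drift_freq, NA_real_),
      drift_phase = ifelse(is_drift, drift_phase, NA_real_),
      drift_amplitude = ifelse(is_drift, A, NA_real_),
      corr_sign = ifelse(classes == "ftoe_correlated", corr_sign, NA_real_),
      compound_code = corr_code),
    planted_pathway = planted_pathway,
    ftoe = data.frame(injection_id = inj$injection_id[st], ftoe = ftoe))
  list(table = feature_table(features, inj, x), truth = truth)
}

#' Simulate a full study (cohort plus both ionization modes)
#'
#' @param params a [simulation_params()].
#' @param drugs,library,planted_pathway passed to [simulate_batch()].
#' @return list: `cohort`, `pos`, `neg` (each `list(table, truth)`),
#'   `drugs`, `library`.
#' @export
simulate_study <- function(params = simulation_params(),
                           drugs = default_drug_list(),
                           library = default_pathway_library(),
                           planted_pathway = "map00030") {
  cohort <- simulate_cohort(params)
  pos <- simulate_batch(cohort, params, "positive", drugs, library,
                        planted_pathway)
  neg <- simulate_batch(cohort, params, "negative", drugs, library,
                        planted_pathway)
  list(cohort = cohort, pos = pos, neg = neg, drugs = drugs,
       library = library)
}

#' Write a simulated study to disk
#'
#' Emits the pipeline's input files: positive/negative peak tables with a
#' shared metadata convention, the clinical sheet, the drug list, the
#' pathway library, and the truth registry as JSON.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_feature_table(sim$pos$table, fp("peaktable_pos.csv"),
                      fp("metadata_pos.tsv"))
  write_feature_table(sim$neg$table, fp("peaktable_neg.csv"),
                      fp("metadata_neg.tsv"))
  utils::write.table(sim$cohort, fp("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$drugs, fp("drug_list.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$library, fp("pathway_library.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(pos = sim$pos$truth, neg = sim$neg$truth)
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "columns",
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}
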