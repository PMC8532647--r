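## QC-SVR intra-batch drift correction.
##
## Each feature's drift is modelled by epsilon-SVR (RBF kernel) of QC
## intensity against injection order, fit on the non-conditioning QC
## injections only.  Scaling conventions (documented in the methods
## vignette): injection order is min-max scaled to [0,1] before the kernel,
## so the gamma grid 1..1e5 spans smooth to near-interpolating fits;
## intensities are scaled to percent of the feature's QC median, so the
## epsilon grid 2.5..7.5 is a 2.5-7.5% insensitivity tube.  The SVR cost C
## is the feature's median QC intensity (effectively unconstrained for
## abundant features).  (epsilon, gamma) are selected per feature by
## leave-one-out RMSE over the grid, ties going to smaller gamma then
## smaller epsilon.

#' Fit a per-feature QC drift model
#'
#' @param orders injection orders of the QC injections (>= 4 required).
#' @param intensities QC intensities of one feature (nonnegative).
#' @param epsilon_grid,gamma_grid hyperparameter grids (see
#'   [pipeline_config()]).
#' @param c_value SVR cost; by convention the median QC intensity of the
#'   feature.  Defaults to `median(intensities)`.
#' @param feature_id optional label carried into the model.
#' @return object of class `drift_model` with elements `epsilon`, `gamma`,
#'   `c`, `loo_rmse`, support values, the scaling constants, and a
#'   `degenerate` flag (TRUE when the QC median is not positive, in which
#'   case no fit is attempted).
#' @export
fit_qcsvr <- function(orders, intensities,
                      epsilon_grid = seq(2.5, 7.5, length.out = 5),
                      gamma_grid = 10^(0:5),
                      c_value = NULL, feature_id = NA_character_) {
  if (length(orders) != length(intensities))
    .fail("orders and intensities lengths differ")
  if (length(orders) < 4L) .fail("QC-SVR needs >= 4 QC injections")
  if (any(intensities < 0)) .fail("negative QC intensity")
  med <- stats::median(intensities)
  if (is.null(c_value)) c_value <- med
  x_min <- min(orders); x_range <- max(orders) - x_min
  model <- list(feature_id = feature_id, c = c_value, qc_median = med,
                qc_orders = orders, x_min = x_min,
                x_range = if (x_range > 0) x_range else 1,
                degenerate = FALSE)
  if (med <= 0 || x_range <= 0 || c_value <= 0) {
    model$degenerate <- TRUE
    model$epsilon <- NA_real_; model$gamma <- NA_real_
    model$loo_rmse <- NA_real_
    class(model) <- "drift_model"
    return(model)
  }
  xs <- (orders - x_min) / model$x_range
  ys <- 100 * intensities / med
  ## C equals the feature's median QC intensity *on the fitting scale*:
  ## scaling y by 100/median maps the raw-scale cost (= median) to 100,
  ## keeping the regularization equivalent to fitting raw intensities with
  ## C = median (SVR is equivariant under joint scaling of y, epsilon, C).
  cost <- 100 * c_value / med
  fit <- cpp_qcsvr_select(xs, ys, sort(epsilon_grid), sort(gamma_grid),
                          cost)
  model[c("epsilon", "gamma", "loo_rmse", "beta", "b")] <-
    fit[c("epsilon", "gamma", "loo_rmse", "beta", "b")]
  model$x_support <- xs
  class(model) <- "drift_model"
  model
}

#' Predict the drift curve at arbitrary injection orders
#'
#' @param model a `drift_model`.
#' @param orders injection orders to predict at.
#' @return predicted intensities on the raw scale of the feature.
#' @export
predict_drift <- function(model, orders) {
  if (model$degenerate)
    return(rep(model$qc_median, length(orders)))
  xq <- (orders - model$x_min) / model$x_range
  pred <- cpp_svr_predict(model$x_support, model$beta, model$b,
                          model$gamma, xq)
  pred * model$qc_median / 100
}

#' Apply a drift model to an intensity series
#'
#' Multiplicative correction normalized to the QC median:
#' `corrected(i) = series(i) / max(pred(i), floor) * median(QC)` with
#' `floor = 1e-6 * median(QC)`, preserving nonnegativity and the feature's
#' intensity scale.  Degenerate models return the series unchanged with
#' attribute `flag = "degenerate"`.
#'
#' @param series intensities over the injections to correct.
#' @param model a `drift_model`.
#' @param orders injection orders matching `series`.
#' @return corrected series.
#' @export
apply_correction <- function(series, model, orders) {
  if (length(series) != length(orders))
    .fail("series and orders lengths differ")
  if (model$degenerate) {
    attr(series, "flag") <- "degenerate"
    return(series)
  }
  pred <- predict_drift(model, orders)
  floor_val <- 1e-6 * model$qc_median
  series / pmax(pred, floor_val) * model$qc_median
}

#' Drift-correct a whole peak table
#'
#' Fits one QC-SVR model per feature on the non-conditioning QC injections
#' and rescales every retained injection.  Conditioning injections are
#' excluded from fitting and dropped from the output (data acquired during
#' system conditioning are discarded from analysis).
#'
#' @param ft a `feature_table` containing >= 4 non-conditioning QCs.
#' @param config a [pipeline_config()].
#' @return list with `table` (corrected, conditioning dropped) and `report`
#'   (data.frame: feature_id, epsilon, gamma, c, loo_rmse, pre_rsd,
#'   post_rsd, degenerate).
#' @export
correct_batch <- function(ft, config = pipeline_config()) {
  validate_feature_table(ft)
  qc <- qc_idx(ft)
  if (length(qc) < 4L) .fail("drift correction needs >= 4 non-conditioning QCs")
  keep <- which(ft$injections$role != "conditioning")
  out <- subset_table(ft, injections = keep)
  orders_all <- out$injections$order
  qc_out <- qc_idx(out)
  qc_orders <- ft$injections$order[qc]
  n_feat <- nrow(ft$features)
  corrected <- out$intensities
  rep_df <- data.frame(feature_id = ft$features$feature_id,
                       epsilon = NA_real_, gamma = NA_real_, c = NA_real_,
                       loo_rmse = NA_real_, pre_rsd = NA_real_,
                       post_rsd = NA_real_, degenerate = FALSE)
  for (f in seq_len(n_feat)) {
    y_qc <- ft$intensities[f, qc]
    model <- fit_qcsvr(qc_orders, y_qc,
                       epsilon_grid = config$svr_epsilon_grid,
                       gamma_grid = config$svr_gamma_grid,
                       feature_id = ft$features$feature_id[f])
    corrected[f, ] <- c(apply_correction(out$intensities[f, ], model,
                                         orders_all))
    rep_df$epsilon[f] <- model$epsilon
    rep_df$gamma[f] <- model$gamma
    rep_df$c[f] <- model$c
    rep_df$loo_rmse[f] <- model$loo_rmse
    rep_df$degenerate[f] <- model$degenerate
    rep_df$pre_rsd[f] <- if (mean(y_qc) > 0) rsd_percent(y_qc) else Inf
    y_post <- corrected[f, qc_out]
    rep_df$post_rsd[f] <- if (mean(y_post) > 0) rsd_percent(y_post) else Inf
  }
  out$intensities <- corrected
  list(table = validate_feature_table(out), report = rep_df)
}
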