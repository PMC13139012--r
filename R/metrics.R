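#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y)^2}. The
#' sum-of-squares form (not the squared correlation), so a biased model can
#' score below zero.
#'
#' @param y observed values (non-constant).
#' @param yhat predictions.
#' @param method `"sse"` (default) or `"cor"` for the squared Pearson
#'   correlation, provided for sensitivity checks.
#' @return scalar R-squared.
#' @export
r_squared <- function(y, yhat, method = c("sse", "cor")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (var(y) == 0) abort("R-squared undefined for constant observations.")
  if (method == "cor") return(stats::cor(y, yhat)^2)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))` with divisor n, the RMSEC/RMSEP convention.
#'
#' @param y observed values.
#' @param yhat predictions.
#' @return scalar RMSE in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (length(y) == 0) abort("RMSE of an empty vector.")
  sqrt(mean((y - yhat)^2))
}

#' Residual predictive deviation
#'
#' RPD = SD of the prediction-set reference values (sample SD, ddof = 1)
#' divided by RMSEP. Values above 2 indicate a model usable for
#' quantification; 1.4-2 for coarse screening.
#'
#' @param y prediction-set reference values (length >= 2).
#' @param rmsep prediction-set RMSE (> 0).
#' @return scalar ratio.
#' @export
rpd <- function(y, rmsep) {
  stopifnot(length(y) >= 2)
  if (rmsep <= 0) abort("RPD undefined for non-positive RMSEP.")
  sd(y) / rmsep
}

#' Range error ratio
#'
#' RER = range (max - min) of the prediction-set reference values divided
#' by RMSEP.
#'
#' @param y prediction-set reference values.
#' @param rmsep prediction-set RMSE (> 0).
#' @return scalar ratio.
#' @export
rer <- function(y, rmsep) {
  if (rmsep <= 0) abort("RER undefined for non-positive RMSEP.")
  (max(y) - min(y)) / rmsep
}

#' Evaluate a fitted model on calibration and prediction sets
#'
#' Computes the full metric row: R2c/RMSEC on the calibration set, R2p/RMSEP
#' on the prediction set, and RPD/RER from the prediction-set reference
#' values. A perfect prediction set (RMSEP = 0) reports `Inf` for RPD/RER.
#'
#' @param model a fitted [plsr_fit()] model.
#' @param x_cal,y_cal calibration spectra and references.
#' @param x_pred,y_pred prediction spectra and references.
#' @param state,chain optional labels carried into the row.
#' @return a one-row tibble with columns `state`, `chain`, `n_lv`, `r2c`,
#'   `rmsec`, `r2p`, `rmsep`, `rpd`, `rer`.
#' @export
evaluate_model <- function(model, x_cal, y_cal, x_pred, y_pred,
                           state = NA_character_, chain = NA_character_) {
  yhat_c <- plsr_predict(model, x_cal)
  yhat_p <- plsr_predict(model, x_pred)
  rmsep <- rmse(y_pred, yhat_p)
  tibble(
    state = state, chain = chain, n_lv = model$n_lv,
    r2c = r_squared(y_cal, yhat_c),
    rmsec = rmse(y_cal, yhat_c),
    r2p = r_squared(y_pred, yhat_p),
    rmsep = rmsep,
    rpd = if (rmsep > 0) rpd(y_pred, rmsep) else Inf,
    rer = if (rmsep > 0) rer(y_pred, rmsep) else Inf
  )
}
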