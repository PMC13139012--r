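#' Plot the spectra of a dataset
#'
#' One line per sample over wavelength, coloured by reference fat value —
#' the standard raw-spectra overview plot.
#'
#' @param object a `nir_dataset`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nir_dataset <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = -dplyr::all_of(meta_columns),
                              names_to = "wavelength", values_to = "absorbance")
  long$wavelength <- as.numeric(long$wavelength)
  ggplot(long, aes(.data$wavelength, .data$absorbance,
                   group = .data$sample_id, colour = .data$fat_percent)) +
    geom_line(alpha = 0.4) +
    labs(x = "Wavelength (nm)", y = "Absorbance (AU)", colour = "Fat (%)") +
    theme_minimal()
}

#' Mahalanobis-distance screening plot
#'
#' Per-sample squared Mahalanobis distance with the confidence limit;
#' flagged samples highlighted — the screening diagnostic view.
#'
#' @param screen_result a [spectral_outliers()] result or the report from
#'   [screen_dataset()].
#' @return a ggplot object.
#' @export
plot_mahalanobis <- function(screen_result) {
  if (!is.null(screen_result$md_diagnostics)) {
    diag <- screen_result$md_diagnostics
    thr <- screen_result$md_threshold
  } else {
    diag <- screen_result$diagnostics
    thr <- screen_result$threshold
  }
  ggplot(diag, aes(.data$sample_id, .data$md_sq, colour = .data$flagged)) +
    geom_point() +
    geom_hline(yintercept = thr, linetype = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    labs(x = "Sample", y = expression(MD^2), colour = "Outlier") +
    theme_minimal()
}

#' Model-grid performance plot
#'
#' Prediction-set R-squared per pretreatment chain and state.
#'
#' @param object a [run_grid()] result (or row-bound metrics of several).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nir_grid <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !.data$failed)
  d$chain <- factor(d$chain, levels = unique(d$chain))
  ggplot(d, aes(.data$chain, .data$r2p, fill = .data$state)) +
    geom_col(position = "dodge") +
    labs(x = "Pretreatment", y = expression(R[p]^2), fill = "State") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Measured-versus-predicted plot
#'
#' Prediction-set scatter with the identity line and the fitted regression
#' line — the standard external-validation view of a calibration model.
#'
#' @param predictions tibble with columns `measured` and `predicted` (the
#'   `predictions` attribute of a [run_grid()] result).
#' @return a ggplot object.
#' @export
plot_predictions <- function(predictions) {
  ggplot(predictions, aes(.data$measured, .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    geom_point() +
    labs(x = "Measured fat (%)", y = "Predicted fat (%)") +
    theme_minimal()
}
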