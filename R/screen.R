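#' Squared Mahalanobis distance in PCA score space
#'
#' For centered scores with per-component variances \eqn{v_k}, the squared
#' Mahalanobis distance of sample i is \eqn{MD^2_i = \sum_k t_{ik}^2 / v_k}.
#' Because scores are uncorrelated by construction, the covariance matrix is
#' diagonal and the distance reduces to this variance-scaled sum; summing
#' over samples gives exactly \eqn{(n - 1) k}.
#'
#' @param scores n x k matrix of (centered) PCA scores.
#' @param score_variances per-component score variances (ddof = 1), all > 0.
#' @return numeric vector of squared distances.
#' @export
mahalanobis_sq <- function(scores, score_variances) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == length(score_variances))
  if (any(score_variances <= 0)) {
    abort(sprintf("Degenerate component %d: zero score variance.",
                  which(score_variances <= 0)[1]))
  }
  as.vector(sweep(scores^2, 2, score_variances, "/") %*% rep(1, ncol(scores)))
}

#' Screening configuration
#'
#' Parameters of the two-stage outlier screen. Defaults follow the
#' pipeline's study conditions: per-state screening pretreatment (vector
#' normalization for in-shell and de-shelled spectra, MSC for granules),
#' Mahalanobis distances in the space of the first `fixed_k = 4` principal
#' components (whose cumulative variance exceeds the 99 % retention rule on
#' this data class), flagging beyond the 95 % confidence limit, then
#' concentration residuals beyond 2.5 sample SDs.
#'
#' @param screening_chains named list mapping each state to a pretreatment
#'   chain label used only for the spectral screen.
#' @param fixed_k number of PCs for the Mahalanobis screen; set to `NULL` to
#'   choose k by the cumulative-variance rule instead.
#' @param pc_threshold cumulative-variance threshold used when
#'   `fixed_k = NULL`.
#' @param md_confidence confidence level of the spectral outlier limit.
#' @param md_method `"chisq"` treats the confidence ellipse as the
#'   chi-square(k) quantile on MD^2 (the large-n reading); `"hotelling"`
#'   uses the Hotelling T^2 / F-distribution small-sample limit.
#' @param residual_multiplier flag chemical outliers beyond this many sample
#'   SDs of the concentration residuals.
#' @param residual_lv latent-variable count of the internal residual model:
#'   `"cv"` for cross-validated selection or a fixed integer.
#' @return a list of class `screening_config`.
#' @export
screening_config <- function(screening_chains = list(in_shell = "Normalize",
                                                     de_shelled = "Normalize",
                                                     granules = "MSC",
                                                     unknown = "Normalize"),
                             fixed_k = 4,
                             pc_threshold = 0.99,
                             md_confidence = 0.95,
                             md_method = c("chisq", "hotelling"),
                             residual_multiplier = 2.5,
                             residual_lv = "cv") {
  stopifnot(md_confidence > 0, md_confidence < 1, residual_multiplier > 0)
  structure(list(
    screening_chains = screening_chains,
    fixed_k = fixed_k,
    pc_threshold = pc_threshold,
    md_confidence = md_confidence,
    md_method = match.arg(md_method),
    residual_multiplier = residual_multiplier,
    residual_lv = residual_lv
  ), class = "screening_config")
}

#' Spectral outlier screen (PCA-Mahalanobis)
#'
#' Applies the state's screening pretreatment, fits a centered PCA on all
#' samples, computes squared Mahalanobis distances in the leading-k score
#' space and flags samples beyond the confidence limit (by default the
#' chi-square quantile with k degrees of freedom at 95 %).
#'
#' @param data a `nir_dataset`.
#' @param cfg a [screening_config()].
#' @return list with `ids` (flagged sample ids), `diagnostics` (tibble of
#'   `sample_id`, `md_sq`, `flagged`), `threshold`, `k` and `pca`.
#' @export
spectral_outliers <- function(data, cfg = screening_config()) {
  state <- data$state[1]
  chain <- cfg$screening_chains[[state]]
  if (is.null(chain)) chain <- "Original"
  X <- apply_chain(chain, spectra_matrix(data),
                   wavelengths = dataset_wavelengths(data))$fit
  pca <- pca_fit(X)
  k <- if (is.null(cfg$fixed_k)) choose_k(pca, cfg$pc_threshold) else
    min(cfg$fixed_k, length(pca$score_variances))
  if (nrow(data) <= k) abort("Need more samples than score-space dimensions.")
  md2 <- mahalanobis_sq(pca$scores[, seq_len(k), drop = FALSE],
                        pca$score_variances[seq_len(k)])
  n <- nrow(data)
  threshold <- if (cfg$md_method == "chisq") {
    qchisq(cfg$md_confidence, df = k)
  } else {
    # Hotelling T^2 prediction limit: k(n^2-1)/(n(n-k)) * F_alpha(k, n-k)
    k * (n^2 - 1) / (n * (n - k)) * qf(cfg$md_confidence, k, n - k)
  }
  flagged <- md2 > threshold
  list(
    ids = sort(data$sample_id[flagged]),
    diagnostics = tibble(sample_id = data$sample_id, md_sq = md2, flagged = flagged),
    threshold = threshold,
    k = as.integer(k),
    chain = chain,
    pca = pca
  )
}

#' Chemical outlier screen (concentration residuals)
#'
#' Screens for reference-assay errors with an internal PLS model of the
#' reference value on the raw spectra (latent-variable count
#' cross-validated by default). The concentration residuals `y - yhat` are
#' computed out-of-fold (5-fold venetian blinds): each sample is predicted
#' by a model fitted without it, so a corrupted reference value cannot be
#' absorbed into its own prediction — an in-sample PLS fit with hundreds of
#' wavelength channels can swallow even a large single-sample shift.
#' Samples whose absolute residual exceeds `residual_multiplier` times the
#' residual sample SD are flagged (single pass, no refitting).
#'
#' @param data a `nir_dataset` with reference values.
#' @param cfg a [screening_config()].
#' @return list with `ids`, `diagnostics` (tibble of `sample_id`,
#'   `residual`, `flagged`), `threshold`, `residual_sd` and `n_lv`.
#' @export
chemical_outliers <- function(data, cfg = screening_config()) {
  if (nrow(data) < 10) abort("Chemical screening needs at least 10 samples.")
  if (anyNA(data$fat_percent)) abort("Chemical screening needs reference values.")
  X <- spectra_matrix(data)
  y <- data$fat_percent
  n <- nrow(X)
  n_lv <- if (identical(cfg$residual_lv, "cv")) {
    select_lv(X, y, lv_grid = 1:10)$n_lv
  } else {
    as.integer(cfg$residual_lv)
  }
  fold <- ((seq_len(n) - 1L) %% 5L) + 1L
  yhat <- numeric(n)
  for (f in unique(fold)) {
    te <- fold == f
    fit <- plsr_fit(X[!te, , drop = FALSE], y[!te],
                    n_lv = min(n_lv, sum(!te) - 1L), on_deficient = "truncate")
    yhat[te] <- plsr_predict(fit, X[te, , drop = FALSE])
  }
  resid <- y - yhat
  res_sd <- sd(resid)
  threshold <- cfg$residual_multiplier * res_sd
  # numerically perfect fits leave only rounding noise: nothing to flag
  flagged <- if (res_sd < 1e-8 * max(sd(y), 1)) rep(FALSE, n) else
    abs(resid) > threshold
  list(
    ids = sort(data$sample_id[flagged]),
    diagnostics = tibble(sample_id = data$sample_id, residual = resid,
                         flagged = flagged),
    threshold = threshold,
    residual_sd = res_sd,
    n_lv = n_lv
  )
}

#' Two-stage outlier screen
#'
#' Runs the spectral (PCA-Mahalanobis) screen first, removes its flags,
#' then runs the chemical (concentration-residual) screen on the surviving
#' samples; the union of both flag lists is removed from the dataset.
#'
#' @param data a `nir_dataset`.
#' @param cfg a [screening_config()].
#' @return list with `data` (clean dataset) and `report`, a list holding
#'   `spectral_ids`, `chemical_ids`, `removed_ids` (ordered union), the two
#'   diagnostics tibbles, both thresholds and a config echo.
#' @export
#' @examples
#' g <- generate_dataset(generator_config(n_samples = 60), "granules", seed = 2)
#' s <- screen_dataset(g$data)
#' s$report$removed_ids
screen_dataset <- function(data, cfg = screening_config()) {
  spec <- spectral_outliers(data, cfg)
  survivors <- data[!data$sample_id %in% spec$ids, ]
  chem <- chemical_outliers(survivors, cfg)
  removed <- sort(union(spec$ids, chem$ids))
  clean <- data[!data$sample_id %in% removed, ]
  if (nrow(clean) == 0) abort("Screening removed every sample.")
  report <- list(
    spectral_ids = spec$ids,
    chemical_ids = chem$ids,
    removed_ids = removed,
    md_threshold = spec$threshold,
    md_k = spec$k,
    md_diagnostics = spec$diagnostics,
    residual_threshold = chem$threshold,
    residual_sd = chem$residual_sd,
    residual_lv = chem$n_lv,
    residual_diagnostics = chem$diagnostics,
    config = cfg
  )
  list(data = clean, report = report)
}

#' Serialize an outlier report to JSON
#' @param report the `report` element of [screen_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  out <- list(
    spectral_outlier_ids = report$spectral_ids,
    chemical_outlier_ids = report$chemical_ids,
    removed_ids = report$removed_ids,
    md_threshold = report$md_threshold,
    md_k = report$md_k,
    md_sq = report$md_diagnostics$md_sq,
    residual_threshold = report$residual_threshold,
    residual_sd = report$residual_sd,
    residual_lv = report$residual_lv,
    residuals = report$residual_diagnostics$residual,
    md_confidence = report$config$md_confidence,
    residual_multiplier = report$config$residual_multiplier
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
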