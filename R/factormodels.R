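#' Principal component analysis of a spectra matrix
#'
#' Mean-centered PCA via singular value decomposition. Components are
#' ordered by decreasing score variance; the sign of each loading is fixed
#' so its largest-magnitude element is positive, making decompositions
#' reproducible across runs and BLAS implementations.
#'
#' @param X spectra matrix (samples x wavelengths), `n >= 2`.
#' @param k_max number of components to retain; defaults to
#'   `min(n - 1, p)`.
#' @return an object of class `nir_pca` with fields `mean` (column means),
#'   `loadings` (p x k, orthonormal columns), `scores` (n x k),
#'   `score_variances` (sample variance of each score, ddof = 1) and
#'   `explained_ratio` (fraction of total centered variance).
#' @export
pca_fit <- function(X, k_max = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) abort("PCA needs at least 2 samples.")
  full_k <- min(n - 1, ncol(X))
  if (is.null(k_max)) k_max <- full_k
  if (k_max < 1) abort("k_max must be >= 1.")
  k_max <- min(k_max, full_k)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = k_max, nv = k_max)
  flip <- vapply(seq_len(k_max), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(k_max), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k_max), drop = FALSE] %*%
                    diag(sv$d[seq_len(k_max)], k_max), 2, flip, "*")
  variances <- sv$d^2 / (n - 1)          # all singular values, for the ratio
  structure(list(
    mean = mu,
    loadings = loadings,
    scores = scores,
    score_variances = variances[seq_len(k_max)],
    explained_ratio = variances[seq_len(k_max)] / sum(variances),
    total_variance = sum(variances),
    n = n
  ), class = "nir_pca")
}

#' Number of components reaching a cumulative-variance threshold
#'
#' Returns the smallest k whose cumulative explained-variance ratio meets
#' the threshold (default 99 %, the usual chemometric retention rule),
#' capped at the number of available components.
#'
#' @param model a [pca_fit()] result.
#' @param threshold cumulative explained-variance fraction in (0, 1].
#' @return integer component count.
#' @export
choose_k <- function(model, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  cum <- cumsum(model$explained_ratio)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  as.integer(k)
}

#' Project new spectra onto fitted principal components
#' @param model a [pca_fit()] result.
#' @param X matrix with the same wavelength columns.
#' @return score matrix (n x k).
#' @export
pca_scores <- function(model, X) {
  sweep(as.matrix(X), 2, model$mean) %*% model$loadings
}

#' @export
tidy.nir_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$explained_ratio),
    score_variance = x$score_variances,
    explained_ratio = x$explained_ratio,
    cumulative_ratio = cumsum(x$explained_ratio)
  )
}

#' @export
glance.nir_pca <- function(x, ...) {
  tibble(n = x$n, n_components = length(x$explained_ratio),
         total_variance = x$total_variance)
}

#' @export
print.nir_pca <- function(x, ...) {
  cat(sprintf("<nir_pca> %d components, first explains %.2f%% of variance\n",
              length(x$explained_ratio), 100 * x$explained_ratio[1]))
  invisible(x)
}

#' Partial least squares regression (NIPALS, single response)
#'
#' Fits a PLS1 model on column-centered spectra and centered response by the
#' NIPALS deflation algorithm: for each component, the weight vector is the
#' (normalized) covariance direction `t(X) y`, scores are `X w`, and X is
#' deflated by the rank-one score/loading product. The regression vector for
#' `k` components is `W (P'W)^{-1} q`, so predictions are
#' `y_mean + (X - x_mean) b`.
#'
#' @param X calibration spectra matrix.
#' @param y reference values (one per row of `X`), non-constant.
#' @param n_lv number of latent variables, `1 <= n_lv < n`.
#' @param on_deficient what to do if a component's residual covariance
#'   collapses below numerical rank: `"error"` (default) or `"truncate"`
#'   to return the model with the components extracted so far.
#' @return an object of class `nir_pls` with fields `x_mean`, `y_mean`,
#'   `weights` (p x k), `x_loadings` (p x k), `y_loadings` (length k),
#'   `coefficients` (regression vector, length p), `n_lv`, and `fitted`.
#' @export
plsr_fit <- function(X, y, n_lv, on_deficient = c("error", "truncate")) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  on_deficient <- match.arg(on_deficient)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (n_lv < 1) abort("n_lv must be >= 1.")
  if (n_lv >= n) abort("n_lv must be smaller than the number of samples.")
  if (var(y) == 0) abort("Response has zero variance.")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  tol <- max(abs(E)) * 1e-12 + 1e-300
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  k_eff <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      if (on_deficient == "truncate") break
      abort(sprintf("Rank deficiency at component %d: residual covariance is zero.", k))
    }
    w <- w / nw
    t_k <- as.vector(E %*% w)
    tt <- sum(t_k^2)
    if (tt < tol^2) {
      if (on_deficient == "truncate") break
      abort(sprintf("Rank deficiency at component %d: degenerate scores.", k))
    }
    p_k <- as.vector(crossprod(E, t_k)) / tt
    q_k <- sum(f * t_k) / tt
    E <- E - tcrossprod(t_k, p_k)
    f <- f - q_k * t_k
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k; Tm[, k] <- t_k
    k_eff <- k
  }
  if (k_eff == 0L) abort("No PLS component could be extracted.")
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  q <- q[seq_len(k_eff)]
  coefs <- pls_coef(W, P, q, k_eff)
  model <- structure(list(
    x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = q,
    scores = Tm[, seq_len(k_eff), drop = FALSE],
    coefficients = coefs[, k_eff],
    coefficient_path = coefs,
    n_lv = k_eff, n = n
  ), class = "nir_pls")
  model$fitted <- plsr_predict(model, X)
  model
}

# regression vectors for components 1..k as columns: b_k = W_k (P_k' W_k)^-1 q_k
pls_coef <- function(W, P, q, k) {
  out <- vapply(seq_len(k), function(j) {
    Wj <- W[, seq_len(j), drop = FALSE]
    Pj <- P[, seq_len(j), drop = FALSE]
    as.vector(Wj %*% solve(crossprod(Pj, Wj), q[seq_len(j)]))
  }, numeric(nrow(W)))
  matrix(out, nrow = nrow(W), ncol = k)
}

#' Predict reference values from spectra
#'
#' @param model a [plsr_fit()] result.
#' @param X matrix of new spectra with the calibration wavelength columns.
#' @param n_lv optionally predict with fewer components than fitted.
#' @return numeric vector of predictions (% w/w).
#' @export
plsr_predict <- function(model, X, n_lv = model$n_lv) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    abort(sprintf("Wavelength mismatch: model has %d columns, data %d.",
                  length(model$x_mean), ncol(X)))
  }
  stopifnot(n_lv >= 1, n_lv <= model$n_lv)
  b <- model$coefficient_path[, n_lv]
  model$y_mean + as.vector(sweep(X, 2, model$x_mean) %*% b)
}

#' @export
predict.nir_pls <- function(object, newdata, ...) plsr_predict(object, newdata, ...)

#' @export
tidy.nir_pls <- function(x, wavelengths = NULL, ...) {
  tibble(
    term = if (is.null(wavelengths)) seq_along(x$coefficients) else wavelengths,
    estimate = x$coefficients
  )
}

#' @export
glance.nir_pls <- function(x, ...) {
  tibble(n = x$n, n_lv = x$n_lv)
}

#' @export
print.nir_pls <- function(x, ...) {
  cat(sprintf("<nir_pls> %d latent variables fitted on %d samples\n", x$n_lv, x$n))
  invisible(x)
}

#' Cross-validated latent-variable selection
#'
#' k-fold cross-validation over a grid of component counts, returning the
#' count minimizing RMSECV (root mean squared error of cross-validation);
#' ties break to the smallest count. Folds are venetian blinds over row
#' order (every `n_folds`-th row), which is fully deterministic; pass a
#' `seed` to use random folds instead.
#'
#' @param X calibration spectra matrix.
#' @param y reference values.
#' @param lv_grid candidate component counts (default 1..15).
#' @param n_folds number of folds (>= 2).
#' @param seed optional integer for random fold assignment.
#' @return list with `n_lv` (selected count) and `rmsecv`, a tibble with
#'   columns `n_lv` and `rmsecv`.
#' @export
select_lv <- function(X, y, lv_grid = 1:15, n_folds = 5, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n_folds >= 2, length(y) == n)
  lv_grid <- sort(unique(as.integer(lv_grid)))
  max_train <- n - ceiling(n / n_folds)
  lv_grid <- lv_grid[lv_grid < max_train]
  if (length(lv_grid) == 0) abort("No feasible latent-variable count for these folds.")
  fold <- ((seq_len(n) - 1L) %% n_folds) + 1L
  if (!is.null(seed)) fold <- fold[order(runif_seeded(n, seed))]
  if (any(tabulate(fold, n_folds) == 0)) abort("Degenerate fold assignment (empty fold).")
  k_max <- max(lv_grid)
  sse <- numeric(k_max)
  for (fid in seq_len(n_folds)) {
    test <- fold == fid
    fit <- plsr_fit(X[!test, , drop = FALSE], y[!test],
                    n_lv = min(k_max, sum(!test) - 1L), on_deficient = "truncate")
    for (k in seq_len(k_max)) {
      kk <- min(k, fit$n_lv)
      pred <- plsr_predict(fit, X[test, , drop = FALSE], n_lv = kk)
      sse[k] <- sse[k] + sum((y[test] - pred)^2)
    }
  }
  curve <- tibble(n_lv = lv_grid, rmsecv = sqrt(sse[lv_grid] / n))
  best <- curve$n_lv[which.min(curve$rmsecv)]
  list(n_lv = as.integer(best), rmsecv = curve)
}

# deterministic uniforms from a private RNG stream, leaving .Random.seed alone
runif_seeded <- function(n, seed) {
  state <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
  })
  set.seed(seed)
  runif(n)
}
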