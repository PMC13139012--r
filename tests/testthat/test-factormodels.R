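test_that("PCA matches an independent eigen-decomposition and reconstructs the data", {
  set.seed(10)
  X <- matrix(rnorm(5 * 4), 5)
  m <- pca_fit(X)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(m$score_variances, ev[seq_along(m$score_variances)],
               tolerance = 1e-10)
  expect_equal(m$explained_ratio, ev[seq_along(m$explained_ratio)] / sum(ev),
               tolerance = 1e-10)

  # completeness: all min(n-1, p) components reproduce the centered matrix
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(m$scores %*% t(m$loadings), Xc, tolerance = 1e-8)

  # orthonormal loadings, uncorrelated scores summing to the total variance
  expect_equal(crossprod(m$loadings), diag(ncol(m$loadings)), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(m$scores))), 1e-10)
  expect_equal(sum(m$score_variances), sum(diag(cov(X))), tolerance = 1e-8)
})

test_that("rank-1 data loads entirely on the first component", {
  v <- rnorm(20)
  X <- outer(c(1, 2, 3, 4), v) + 5
  m <- pca_fit(X)
  expect_equal(m$explained_ratio[1], 1.0, tolerance = 1e-12)
})

test_that("PCA sign convention makes runs reproducible", {
  set.seed(11)
  X <- matrix(rnorm(30 * 8), 30)
  m1 <- pca_fit(X)
  m2 <- pca_fit(X[sample(30), ])
  expect_equal(abs(m1$loadings), abs(m2$loadings), tolerance = 1e-8)
  # largest-magnitude element positive in every column
  expect_true(all(apply(m1$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("choose_k finds the first cumulative-variance crossing", {
  fake <- structure(list(explained_ratio = c(0.8864, 0.07, 0.03, 0.0100, 0.003)),
                    class = "nir_pca")
  expect_equal(choose_k(fake, 0.99), 4L)
  expect_equal(choose_k(structure(list(explained_ratio = 1.0), class = "nir_pca")), 1L)
  expect_equal(choose_k(structure(list(explained_ratio = c(0.4, 0.2, 0.2, 0.2)),
                                  class = "nir_pca"), 0.5), 2L)
})

test_that("PLS collapses to simple regression on one predictor and to OLS at full rank", {
  set.seed(12)
  x <- rnorm(30)
  y <- 2 + 3 * x + rnorm(30, sd = 0.1)
  m <- plsr_fit(cbind(x), y, n_lv = 1)
  expect_equal(m$coefficients, coef(lm(y ~ x))[2], tolerance = 1e-10,
               ignore_attr = TRUE)

  X <- matrix(rnorm(40 * 5), 40)
  y <- rnorm(40)
  m5 <- plsr_fit(X, y, n_lv = 5)
  expect_equal(m5$fitted, unname(fitted(lm(y ~ X))), tolerance = 1e-6)
})

test_that("noiseless linear responses are recovered exactly at the generating rank", {
  set.seed(13)
  L <- matrix(rnorm(3 * 50), 3)        # 3 latent factors over 50 channels
  Tn <- matrix(rnorm(25 * 3), 25)
  X <- Tn %*% L
  y <- as.vector(Tn %*% c(1, -2, 0.5))
  m <- plsr_fit(X, y, n_lv = 3)
  expect_lt(rmse(y, m$fitted), 1e-8)
})

test_that("stored regression vector reproduces fitted values and centering maps to the mean", {
  g <- generate_dataset(tiny_config(20), "granules", seed = 14)
  X <- spectra_matrix(g$data)
  y <- g$data$fat_percent
  m <- plsr_fit(X, y, n_lv = 4)
  expect_equal(plsr_predict(m, X), m$fitted, tolerance = 1e-8)
  expect_equal(plsr_predict(m, rbind(m$x_mean)), m$y_mean, tolerance = 1e-8)
  expect_error(plsr_predict(m, X[, 1:10]), "mismatch")

  # component-by-component score projection oracle
  Xc <- sweep(X, 2, m$x_mean)
  pred <- rep(m$y_mean, nrow(X))
  E <- Xc
  for (k in seq_len(m$n_lv)) {
    t_k <- E %*% m$weights[, k]
    pred <- pred + as.vector(t_k) * m$y_loadings[k]
    E <- E - t_k %*% t(m$x_loadings[, k])
  }
  expect_equal(pred, plsr_predict(m, X), tolerance = 1e-8)
})

test_that("training fit improves monotonically with more latent variables", {
  set.seed(15)
  X <- matrix(rnorm(30 * 20), 30)
  y <- rnorm(30)
  rmsec <- sapply(1:10, function(k) rmse(y, plsr_fit(X, y, k)$fitted))
  expect_true(all(diff(rmsec) < 1e-10))
})

test_that("rank deficiency errors by default and truncates on request", {
  X <- cbind(rnorm(10))
  y <- 2 * X[, 1]
  expect_error(plsr_fit(X, y, n_lv = 3), "Rank deficiency")
  m <- plsr_fit(X, y, n_lv = 3, on_deficient = "truncate")
  expect_lte(m$n_lv, 2)
  expect_error(plsr_fit(X, rep(1, 10), 1), "variance")
})

test_that("cross-validation selects the generating number of factors", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    L <- matrix(rnorm(3 * 40), 3)
    Tn <- matrix(rnorm(36 * 3), 36)
    X <- Tn %*% L
    y <- as.vector(Tn %*% c(2, -1, 0.7))
    sel <- select_lv(X, y, lv_grid = 1:8)
    if (sel$n_lv == 3) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90 % of seeds
})

test_that("select_lv matches a hand-rolled fold loop and handles edge grids", {
  g <- generate_dataset(tiny_config(20), "granules", seed = 16)
  X <- spectra_matrix(g$data)
  y <- g$data$fat_percent
  sel <- select_lv(X, y, lv_grid = 1:4, n_folds = 5)
  # oracle: same venetian-blind folds, independent loop
  fold <- ((seq_len(20) - 1L) %% 5L) + 1L
  for (k in 1:4) {
    sse <- 0
    for (f in 1:5) {
      te <- fold == f
      fit <- plsr_fit(X[!te, ], y[!te], n_lv = k)
      sse <- sse + sum((y[te] - plsr_predict(fit, X[te, , drop = FALSE]))^2)
    }
    expect_equal(sel$rmsecv$rmsecv[k], sqrt(sse / 20), tolerance = 1e-10)
  }
  expect_equal(select_lv(X, y, lv_grid = 1)$n_lv, 1L)
})
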