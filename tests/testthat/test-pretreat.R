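test_that("SNV centers and scales rows, is affine-invariant and idempotent", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  X <- matrix(rnorm(20 * 50), 20)
  out <- snv(X)
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)
  expect_equal(snv(5 * X + 7), out)
  expect_equal(snv(out), out)
  expect_error(snv(matrix(1, 2, 4)), "row 1")
})

test_that("MSC reference is the calibration mean and corrections match the normal equations", {
  r <- c(1, 2, 3, 4)
  expect_equal(msc_fit(rbind(r, r)), r, ignore_attr = TRUE)
  expect_equal(msc_fit(rbind(r, 3 * r)), 2 * r, ignore_attr = TRUE)
  # spectra-like rows: scatter-transformed copies of a base shape, so the
  # per-row regression slopes are bounded away from zero as MSC assumes
  set.seed(1)
  base <- sin(seq(0, 3, length.out = 40)) + 1.5
  X <- outer(runif(15, 0.7, 1.3), base) + runif(15, -0.3, 0.3) +
    matrix(rnorm(15 * 40, sd = 0.05), 15)
  expect_equal(msc_fit(X), colMeans(X))
  expect_error(msc_fit(X[0, , drop = FALSE]), "2 calibration")

  ref <- colMeans(X)
  expect_equal(msc_apply(rbind(ref), ref), rbind(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(msc_apply(rbind(2 * ref + 3), ref), rbind(ref),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(msc_apply(X, ref), msc_oracle(X, ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Savitzky-Golay reproduces polynomials, scales derivatives per nm, and matches the windowed oracle", {
  w <- seq(1000, 1060, by = 2)  # 2 nm grid to exercise the step scaling
  quad <- outer(c(1, 2), w^2 * 1e-4) + outer(c(0.5, -1), w) * 1e-2
  sm <- savitzky_golay(quad, window = 11, polyorder = 2, deriv = 0, step = 2)
  expect_equal(sm, quad, tolerance = 1e-8)

  line <- rbind(0.3 + 0.005 * w)
  d1 <- savitzky_golay(line, window = 11, polyorder = 2, deriv = 1, step = 2)
  expect_equal(d1, rbind(rep(0.005, length(w))), tolerance = 1e-10)

  set.seed(3)
  x <- rnorm(60)
  for (spec in list(c(11, 2, 0), c(11, 2, 1), c(11, 3, 2))) {
    got <- savitzky_golay(rbind(x), spec[1], spec[2], spec[3], step = 1.5)[1, ]
    want <- sg_oracle(x, spec[1], spec[2], spec[3], step = 1.5)
    interior <- 6:55  # edge handling may differ from the centred-window oracle
    expect_equal(got[interior], want[interior], tolerance = 1e-8)
  }

  expect_error(savitzky_golay(rbind(x), window = 10), "odd")
  expect_error(savitzky_golay(rbind(x), window = 11, polyorder = 11), "polyorder")
  expect_error(savitzky_golay(rbind(x), window = 11, polyorder = 2, deriv = 3),
               "deriv")
})

test_that("vector normalization yields unit rows and is scale-invariant", {
  expect_equal(normalize_rows(matrix(c(3, 4), 1)), matrix(c(0.6, 0.8), 1))
  set.seed(4)
  X <- matrix(rnorm(10 * 30), 10)
  out <- normalize_rows(X)
  expect_lt(max(abs(sqrt(rowSums(out^2)) - 1)), 1e-12)
  expect_equal(normalize_rows(10 * X), out)
  expect_error(normalize_rows(matrix(0, 1, 3)), "row 1")
})

test_that("baseline detrend removes any linear ramp and leaves residuals orthogonal to {1, lambda}", {
  w <- seq(1000, 1100, by = 5)
  line <- rbind(2 + 0.01 * w, -1 + 0.003 * w)
  expect_equal(baseline_detrend(line, w), matrix(0, 2, length(w)),
               tolerance = 1e-10)
  set.seed(5)
  X <- matrix(rnorm(6 * length(w)), 6)
  ramped <- X + cbind(rep(1, 6)) %*% rbind(3 + 0.02 * w)
  expect_equal(baseline_detrend(ramped, w), baseline_detrend(X, w),
               tolerance = 1e-9)
  out <- baseline_detrend(X, w)
  refit <- apply(out, 1, function(r) coef(lm(r ~ w)))
  expect_lt(max(abs(refit)), 1e-10)
})

test_that("chains compose left-to-right and fit MSC on the fit set only", {
  set.seed(6)
  w <- seq(1000, 1100, by = 2)
  X <- matrix(rnorm(12 * length(w), mean = 1), 12)
  Y <- matrix(rnorm(5 * length(w), mean = 1), 5)

  empty <- apply_chain("Original", X, Y, wavelengths = w)
  expect_equal(empty$fit, X)
  expect_equal(empty$new, Y)

  combo <- apply_chain("SG + SNV", X, wavelengths = w)
  manual <- snv(savitzky_golay(X, 11, 2, 0, step = 2))
  expect_equal(combo$fit, manual)

  msc <- apply_chain("MSC", X, Y, wavelengths = w)
  ref <- colMeans(X)
  expect_equal(msc$fit, msc_oracle(X, ref), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(msc$new, msc_oracle(Y, ref), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(preprocess_chain("OSC"), "Unknown")
})

test_that("pretreatment operators are row-wise: permuting samples permutes outputs", {
  set.seed(7)
  w <- seq(1000, 1050)
  X <- matrix(rnorm(9 * length(w), mean = 2), 9)
  perm <- sample(9)
  for (chain in c("SNV", "SG", "Normalize", "Baseline", "1-Der")) {
    out <- apply_chain(chain, X, wavelengths = w)$fit
    out_p <- apply_chain(chain, X[perm, ], wavelengths = w)$fit
    expect_equal(out_p, out[perm, ], tolerance = 1e-12, label = chain)
  }
})

test_that("no pretreatment changes the matrix shape", {
  g <- generate_dataset(tiny_config(10), "granules", seed = 9)
  X <- spectra_matrix(g$data)
  w <- dataset_wavelengths(g$data)
  for (chain in chain_vocabulary()) {
    out <- apply_chain(chain, X, wavelengths = w)$fit
    expect_equal(dim(out), dim(X), label = chain)
  }
})
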