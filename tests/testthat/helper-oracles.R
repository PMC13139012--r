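# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and the library shortcuts they wrap).

# small generator config for fast tests
tiny_config <- function(n = 30, ...) {
  generator_config(n_samples = n, n_spectral_outliers = 0,
                   n_chemical_outliers = 0, ...)
}

# Savitzky-Golay by explicit per-window polynomial least squares:
# fit a polynomial to each window with lm(), read the derivative at the
# evaluation point from the coefficients.
sg_oracle <- function(x, window, polyorder, deriv, step = 1) {
  n <- length(x)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - half), n - window + 1)
    idx <- lo:(lo + window - 1)
    z <- (idx - i) * step                 # local coordinate centered on point i
    fit <- lm(x[idx] ~ poly(z, polyorder, raw = TRUE))
    out[i] <- coef(fit)[deriv + 1] * factorial(deriv)
  }
  out
}

# per-row MSC coefficients by explicit normal equations
msc_oracle <- function(X, reference) {
  t(apply(X, 1, function(x) {
    A <- cbind(1, reference)
    ab <- solve(t(A) %*% A, t(A) %*% x)
    (x - ab[1]) / ab[2]
  }))
}

# SPXY greedy selection by a double-loop, set-based search
spxy_oracle <- function(X, y, n_cal) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  Dy <- abs(outer(y, y, "-"))
  D <- D / max(D) + Dy / max(Dy)
  sel <- integer(0)
  best <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > best) { best <- D[i, j]; sel <- c(i, j) }
  }
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(dmin)])
  }
  sel
}

# chi-square quantile from first principles: hand-coded density integrated
# numerically, root-found on the CDF.
chisq_quantile_oracle <- function(p, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  cdf <- function(q) integrate(dens, 0, q, rel.tol = 1e-10)$value
  uniroot(function(q) cdf(q) - p, c(1e-6, 200), tol = 1e-9)$root
}

# mean and SD of a truncated normal by numerical quadrature
truncnorm_moments_oracle <- function(mean, sd, lo, hi) {
  z <- integrate(function(x) dnorm(x, mean, sd), lo, hi)$value
  m1 <- integrate(function(x) x * dnorm(x, mean, sd), lo, hi)$value / z
  m2 <- integrate(function(x) x^2 * dnorm(x, mean, sd), lo, hi)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# minimal JCAMP-DX writer used only to build test fixtures
write_jcamp_fixture <- function(path, x, y, xfactor = 1, yfactor = 1) {
  lines <- c(
    "##TITLE=synthetic test spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    sprintf("##FIRSTX=%g", x[1] / xfactor),
    sprintf("##LASTX=%g", x[length(x)] / xfactor),
    sprintf("##NPOINTS=%d", length(x)),
    sprintf("##XFACTOR=%g", xfactor),
    sprintf("##YFACTOR=%g", yfactor),
    "##XYDATA=(X++(Y..Y))",
    paste(c(x[1] / xfactor, y / yfactor), collapse = " "),
    "##END="
  )
  writeLines(lines, path)
  path
}
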