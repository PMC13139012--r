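#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum (row) to zero mean and unit sample SD
#' (ddof = 1), removing per-spectrum additive offsets and multiplicative
#' scatter. Idempotent and invariant to affine transforms of a row.
#'
#' @param X spectra matrix (samples x wavelengths).
#' @return matrix of the same shape with row means 0 and row SDs 1.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  if (any(s == 0)) {
    abort(sprintf("SNV undefined for constant spectrum in row %d.", which(s == 0)[1]))
  }
  (X - mu) / s
}

#' Fit the MSC reference spectrum
#'
#' The multiplicative scatter correction reference is the column-mean
#' spectrum of the calibration matrix; it is fitted once on calibration data
#' and reused for any set transformed later.
#'
#' @param X calibration spectra matrix with at least 2 rows.
#' @return numeric vector: the mean spectrum.
#' @export
msc_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("MSC reference needs at least 2 calibration spectra.")
  colMeans(X)
}

#' Apply multiplicative scatter correction
#'
#' Regresses each spectrum on the reference (`x ~ a + b * reference`, least
#' squares) and returns `(x - a) / b`, removing the per-spectrum additive
#' and multiplicative scatter components.
#'
#' @param X spectra matrix.
#' @param reference reference spectrum from [msc_fit()].
#' @param tol slopes with `|b| < tol` raise an uncorrectable-spectrum error.
#' @return corrected matrix of the same shape.
#' @export
msc_apply <- function(X, reference, tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(reference))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) abort("MSC reference spectrum is constant.")
  b <- as.vector(X %*% rc) / denom            # slope of x ~ a + b * ref
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < tol)) {
    abort(sprintf("MSC slope below tolerance for row %d.", which(abs(b) < tol)[1]))
  }
  (X - a) / b
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering applied to each spectrum, with
#' same-length output: edge points come from the local polynomial evaluated
#' at the edge positions, so wavelength alignment is preserved. Derivatives
#' are returned per nm (scaled by `step^-deriv`).
#'
#' @param X spectra matrix.
#' @param window odd filter length (points); default 11.
#' @param polyorder local polynomial order; must satisfy
#'   `deriv <= polyorder < window`.
#' @param deriv derivative order (0 = smoothing).
#' @param step wavelength grid spacing in nm.
#' @return filtered matrix of the same shape.
#' @export
savitzky_golay <- function(X, window = 11, polyorder = 2, deriv = 0, step = 1) {
  X <- as.matrix(X)
  if (window %% 2 == 0 || window < 3) abort("`window` must be odd and >= 3.")
  if (window > ncol(X)) abort("`window` exceeds the number of wavelengths.")
  if (polyorder >= window) abort("`polyorder` must be smaller than `window`.")
  if (deriv > polyorder) abort("`deriv` cannot exceed `polyorder`.")
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window, m = deriv, ts = step))
}

#' Row-wise normalization
#'
#' Default `"vector"` method divides each spectrum by its Euclidean norm
#' (unit-vector normalization); alternatives are `"minmax"` (rescale to
#' `[0, 1]`) and `"area"` (divide by the sum of absolute values).
#'
#' @param X spectra matrix.
#' @param method normalization variant.
#' @return normalized matrix of the same shape.
#' @export
normalize_rows <- function(X, method = c("vector", "minmax", "area")) {
  X <- as.matrix(X)
  method <- match.arg(method)
  switch(method,
    vector = {
      nrm <- sqrt(rowSums(X^2))
      if (any(nrm == 0)) abort(sprintf("All-zero spectrum in row %d.", which(nrm == 0)[1]))
      X / nrm
    },
    minmax = {
      rng <- apply(X, 1, function(r) diff(range(r)))
      if (any(rng == 0)) abort(sprintf("Constant spectrum in row %d.", which(rng == 0)[1]))
      (X - apply(X, 1, min)) / rng
    },
    area = {
      s <- rowSums(abs(X))
      if (any(s == 0)) abort(sprintf("All-zero spectrum in row %d.", which(s == 0)[1]))
      X / s
    }
  )
}

#' Linear baseline detrend
#'
#' Fits and subtracts a least-squares straight line in wavelength from each
#' spectrum, removing the offset-plus-drift component attributed to
#' scattering. Output rows are orthogonal to both the constant and the
#' linear wavelength term.
#'
#' @param X spectra matrix.
#' @param wavelengths wavelength grid (nm), one per column.
#' @return detrended matrix of the same shape.
#' @export
baseline_detrend <- function(X, wavelengths) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(wavelengths), length(wavelengths) >= 2)
  wc <- wavelengths - mean(wavelengths)
  slope <- as.vector(X %*% wc) / sum(wc^2)
  X - rowMeans(X) - outer(slope, wc)
}

#' The pretreatment vocabulary of the modeling grid
#'
#' @return character vector of the 11 chain labels the grid runs, in display
#'   order: `Original`, `1-Der`, `2-Der`, `SG`, `Normalize`, `Baseline`,
#'   `SNV`, `MSC`, `1-Der + SNV`, `2-Der + SNV`, `SG + SNV`.
#' @export
chain_vocabulary <- function() {
  c("Original", "1-Der", "2-Der", "SG", "Normalize", "Baseline",
    "SNV", "MSC", "1-Der + SNV", "2-Der + SNV", "SG + SNV")
}

#' Build a pretreatment chain from its label
#'
#' Parses chain labels such as `"SG + SNV"` into an ordered list of steps
#' applied left to right. Step defaults: SG smoothing window 11, order 2;
#' first derivative window 11, order 2; second derivative window 11,
#' order 3 (all Savitzky-Golay filters, derivatives per nm).
#'
#' @param name a chain label; individual step names may be combined with
#'   `" + "`.
#' @return a list of class `preprocess_chain` with elements `name` and
#'   `steps`.
#' @export
preprocess_chain <- function(name) {
  parts <- trimws(strsplit(name, "\\+")[[1]])
  steps <- lapply(parts, function(part) {
    switch(part,
      "Original" = NULL,
      "SG" = list(kind = "sg", window = 11, polyorder = 2, deriv = 0),
      "1-Der" = list(kind = "sg", window = 11, polyorder = 2, deriv = 1),
      "2-Der" = list(kind = "sg", window = 11, polyorder = 3, deriv = 2),
      "SNV" = list(kind = "snv"),
      "MSC" = list(kind = "msc"),
      "Normalize" = list(kind = "normalize", method = "vector"),
      "Baseline" = list(kind = "baseline"),
      abort(sprintf("Unknown pretreatment \"%s\".", part))
    )
  })
  structure(list(name = name, steps = steps[!vapply(steps, is.null, logical(1))]),
            class = "preprocess_chain")
}

#' Apply a pretreatment chain with calibration-only fitting
#'
#' Applies the chain's steps left to right. Steps that require fitting (the
#' MSC reference) are fitted on `x_fit` only and then applied to both
#' matrices, so no information leaks from `x_new` into the fitted
#' parameters.
#'
#' @param chain a [preprocess_chain()] or chain label.
#' @param x_fit calibration spectra matrix (also the fitting set).
#' @param x_new optional second matrix transformed with parameters fitted on
#'   `x_fit`.
#' @param wavelengths wavelength grid (nm), needed by baseline detrending
#'   and derivative scaling.
#' @return list with `fit` (transformed `x_fit`), `new` (transformed
#'   `x_new`, or `NULL`) and `chain` (with fitted state recorded).
#' @export
apply_chain <- function(chain, x_fit, x_new = NULL,
                        wavelengths = seq_len(ncol(x_fit))) {
  if (is.character(chain)) chain <- preprocess_chain(chain)
  step_apply <- function(step, X) {
    switch(step$kind,
      sg = savitzky_golay(X, step$window, step$polyorder, step$deriv,
                          step = if (length(wavelengths) > 1) diff(wavelengths)[1] else 1),
      snv = snv(X),
      msc = msc_apply(X, step$reference),
      normalize = normalize_rows(X, step$method),
      baseline = baseline_detrend(X, wavelengths)
    )
  }
  for (i in seq_along(chain$steps)) {
    step <- chain$steps[[i]]
    if (step$kind == "msc") {
      step$reference <- msc_fit(x_fit)
      chain$steps[[i]] <- step
    }
    x_fit <- step_apply(step, x_fit)
    if (!is.null(x_new)) x_new <- step_apply(step, x_new)
  }
  list(fit = x_fit, new = x_new, chain = chain)
}

#' Pretreat a spectral dataset
#'
#' Data-frame interface to [apply_chain()]: transforms the absorbance block
#' of a `nir_dataset` in place (fit and transform on the same data).
#'
#' @param data a `nir_dataset`.
#' @param chain a chain label (see [chain_vocabulary()]) or
#'   [preprocess_chain()].
#' @return the pretreated dataset.
#' @export
#' @examples
#' g <- generate_dataset(generator_config(n_samples = 12), "granules", seed = 4)
#' pretreat(g$data, "SNV")
pretreat <- function(data, chain) {
  res <- apply_chain(chain, spectra_matrix(data),
                     wavelengths = dataset_wavelengths(data))
  set_spectra(data, res$fit)
}
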