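#' Soxhlet gravimetric fat content
#'
#' Computes fat content from a Soxhlet extraction weighing:
#' \eqn{F = (m_1 - m_0) / m \times 100}, where \eqn{m_0} is the mass of the
#' empty receiving flask (g), \eqn{m_1} the mass of the flask plus extracted
#' fat (g) and \eqn{m} the sample mass (g). All arguments are vectorized.
#'
#' @param m0 mass of the empty receiving flask (g).
#' @param m1 mass of the flask plus extracted fat (g); must be `>= m0`.
#' @param m sample mass (g); must be `> 0`.
#' @return fat content in % w/w.
#' @export
#' @examples
#' soxhlet_fat(m0 = 100, m1 = 101.1, m = 2)  # 55 %
soxhlet_fat <- function(m0, m1, m) {
  if (any(m <= 0)) abort("Sample mass `m` must be positive.")
  if (any(m1 < m0)) abort("Flask-plus-fat mass `m1` cannot be below the empty-flask mass `m0`.")
  (m1 - m0) / m * 100
}

#' Synthetic-dataset generator configuration
#'
#' Bundles every knob of the synthetic portable-NIR generator. The defaults
#' encode the study conditions the pipeline is designed around: 210 samples
#' on a 1000-1650 nm grid at 1 nm (651 points), Soxhlet fat references drawn
#' from a normal distribution with mean 54.63 % and SD 11.2 truncated to
#' the observed range 40.85-75.43 %, Gaussian absorption bands near 1200 nm
#' (fat-coupled ester C-O-C band) and 1450 nm (predominantly fat-independent
#' O-H/N-H matrix band), triplicate-scan averaging, and per-state scatter,
#' baseline, attenuation, noise and mean-level parameters reproducing the
#' qualitative state phenomenology: mean absorbance granules > de-shelled >
#' in-shell, and scatter/noise in-shell > de-shelled > granules.
#'
#' @param n_samples number of samples per dataset.
#' @param wavelength_start,wavelength_stop,wavelength_step grid in nm.
#' @param fat_mean,fat_sd,fat_min,fat_max truncated-normal reference
#'   distribution parameters (% w/w).
#' @param bands data frame with columns `center` (nm), `width` (Gaussian SD,
#'   nm), `fat_amp` (AU at fat = 100 %), `base_amp` (fat-independent AU).
#' @param background length-3 numeric: constant, linear and quadratic
#'   coefficients of the smooth baseline over the scaled wavelength
#'   `(lambda - mid) / halfspan` in \eqn{[-1, 1]}.
#' @param state_params named list (one entry per state) of lists with fields
#'   `scatter_sd` (multiplicative), `offset_sd` (AU), `slope_sd` (AU/nm),
#'   `attenuation` (multiplier in (0, 1]), `noise_sd` (AU, per replicate
#'   scan) and `level_shift` (AU).
#' @param n_spectral_outliers,n_chemical_outliers planted outlier counts.
#' @param spectral_magnitude AU amplitude of the planted spectral artifact.
#' @param chemical_magnitude absolute reference-value shift (% points).
#' @param replicate_count scans averaged per sample.
#' @param seed default seed used by [generate_dataset()].
#' @return a list of class `nir_generator_config`.
#' @export
generator_config <- function(n_samples = 210,
                             wavelength_start = 1000,
                             wavelength_stop = 1650,
                             wavelength_step = 1,
                             fat_mean = 54.63, fat_sd = 11.2,
                             fat_min = 40.85, fat_max = 75.43,
                             bands = data.frame(
                               center = c(1200, 1450),
                               width = c(40, 55),
                               fat_amp = c(0.16, 0.02),
                               base_amp = c(0.04, 0.30)
                             ),
                             background = c(0.12, 0.015, 0.04),
                             state_params = default_state_params(),
                             n_spectral_outliers = 2,
                             n_chemical_outliers = 3,
                             spectral_magnitude = 0.8,
                             chemical_magnitude = 15,
                             replicate_count = 3,
                             seed = 1L) {
  cfg <- list(
    n_samples = n_samples,
    wavelength_start = wavelength_start,
    wavelength_stop = wavelength_stop,
    wavelength_step = wavelength_step,
    fat_mean = fat_mean, fat_sd = fat_sd,
    fat_min = fat_min, fat_max = fat_max,
    bands = as.data.frame(bands),
    background = background,
    state_params = state_params,
    n_spectral_outliers = n_spectral_outliers,
    n_chemical_outliers = n_chemical_outliers,
    spectral_magnitude = spectral_magnitude,
    chemical_magnitude = chemical_magnitude,
    replicate_count = replicate_count,
    seed = seed
  )
  class(cfg) <- "nir_generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default per-state physical-effect parameters
#'
#' Magnitudes follow the physical reading of the three sample states: the
#' hard shell scatters and attenuates most (largest scatter/offset/noise,
#' strongest attenuation, lowest mean level); grinding to granules maximizes
#' light-matrix contact (highest mean level, least scatter and noise).
#'
#' @return named list with entries `in_shell`, `de_shelled`, `granules`.
#' @export
default_state_params <- function() {
  list(
    in_shell = list(scatter_sd = 0.10, offset_sd = 0.06, slope_sd = 2.5e-4,
                    attenuation = 0.80, noise_sd = 0.075, level_shift = 0.00),
    de_shelled = list(scatter_sd = 0.06, offset_sd = 0.04, slope_sd = 1.5e-4,
                      attenuation = 0.92, noise_sd = 0.065, level_shift = 0.12),
    granules = list(scatter_sd = 0.04, offset_sd = 0.025, slope_sd = 1.0e-4,
                    attenuation = 1.00, noise_sd = 0.045, level_shift = 0.25)
  )
}

validate_generator_config <- function(cfg) {
  grid <- config_wavelengths(cfg)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    abort("Wavelength grid must be strictly increasing with at least 2 points.")
  }
  if (!(cfg$fat_min < cfg$fat_mean && cfg$fat_mean < cfg$fat_max)) {
    abort("Need fat_min < fat_mean < fat_max.")
  }
  if (cfg$fat_sd < 0) abort("fat_sd must be >= 0.")
  if (nrow(cfg$bands) < 1) abort("At least one absorption band is required.")
  for (s in names(cfg$state_params)) {
    p <- cfg$state_params[[s]]
    sds <- c(p$scatter_sd, p$offset_sd, p$slope_sd, p$noise_sd)
    if (any(sds < 0)) abort(sprintf("Negative SD in state_params$%s.", s))
    if (p$attenuation <= 0 || p$attenuation > 1) {
      abort(sprintf("attenuation for state %s must be in (0, 1].", s))
    }
  }
  if (cfg$n_spectral_outliers + cfg$n_chemical_outliers > cfg$n_samples) {
    abort("More planted outliers than samples.")
  }
  if (cfg$n_spectral_outliers > 0 && cfg$spectral_magnitude <= 0) {
    abort("spectral_magnitude must be > 0 when spectral outliers are planted.")
  }
  if (cfg$n_chemical_outliers > 0 && cfg$chemical_magnitude <= 0) {
    abort("chemical_magnitude must be > 0 when chemical outliers are planted.")
  }
  invisible(cfg)
}

config_wavelengths <- function(cfg) {
  seq(cfg$wavelength_start, cfg$wavelength_stop, by = cfg$wavelength_step)
}

#' Draw reference fat values from the truncated-normal model
#'
#' Samples `n` values from a normal(`fat_mean`, `fat_sd`) truncated to
#' `[fat_min, fat_max]` by inverse-CDF transform, so every draw lies inside
#' the configured range. With `fat_sd = 0` all values equal `fat_mean`.
#'
#' @param n number of values.
#' @param cfg a [generator_config()].
#' @return numeric vector of fat references (% w/w).
#' @export
sample_fat_values <- function(n, cfg = generator_config()) {
  stopifnot(n >= 1)
  if (cfg$fat_min >= cfg$fat_max) abort("Need fat_min < fat_max.")
  if (cfg$fat_sd == 0) return(rep(cfg$fat_mean, n))
  plo <- pnorm(cfg$fat_min, cfg$fat_mean, cfg$fat_sd)
  phi <- pnorm(cfg$fat_max, cfg$fat_mean, cfg$fat_sd)
  u <- runif(n, plo, phi)
  qnorm(u, cfg$fat_mean, cfg$fat_sd)
}

#' Noise-free spectra for given fat values
#'
#' Builds the deterministic part of the spectral model: for each fat value
#' \eqn{f}, absorbance at wavelength \eqn{\lambda} is the sum over bands of
#' \eqn{(\code{fat\_amp} \cdot f / 100 + \code{base\_amp}) \,
#' \exp(-(\lambda - c)^2 / (2 w^2))} plus a smooth quadratic background.
#' Absorbance at every wavelength is therefore affine in fat.
#'
#' @param fat numeric vector of fat values (% w/w).
#' @param cfg a [generator_config()].
#' @return matrix `length(fat)` x `p` of absorbances (AU).
#' @export
synthesize_clean_spectrum <- function(fat, cfg = generator_config()) {
  if (nrow(cfg$bands) == 0) abort("Empty band list.")
  w <- config_wavelengths(cfg)
  u <- (w - mean(range(w))) / (diff(range(w)) / 2)  # scaled to [-1, 1]
  bg <- cfg$background[1] + cfg$background[2] * u + cfg$background[3] * u^2
  shapes <- vapply(seq_len(nrow(cfg$bands)), function(i) {
    b <- cfg$bands[i, ]
    exp(-(w - b$center)^2 / (2 * b$width^2))
  }, numeric(length(w)))                       # p x n_bands
  amp_fat <- cfg$bands$fat_amp
  amp_base <- cfg$bands$base_amp
  # n x p: outer(fat/100, amp_fat) %*% t(shapes) + base bands + background
  X <- (outer(fat / 100, amp_fat) + matrix(amp_base, length(fat),
                                           length(amp_base), byrow = TRUE)) %*% t(shapes)
  sweep(X, 2, bg, "+")
}

#' Apply state-dependent physical effects to clean spectra
#'
#' Implements the measurement model for one replicate scan of each row of
#' `S`: \eqn{a_i (\alpha \, s_i(\lambda)) + b_i + d_i (\lambda -
#' \bar\lambda) + \mu + \epsilon_{i\lambda}} with per-spectrum multiplicative
#' scatter \eqn{a_i \sim N(1, \code{scatter\_sd})}, baseline offset
#' \eqn{b_i \sim N(0, \code{offset\_sd})}, baseline tilt \eqn{d_i \sim N(0,
#' \code{slope\_sd})}, state attenuation \eqn{\alpha}, mean-level shift
#' \eqn{\mu} and iid noise of SD `noise_sd`. With all SDs and the shift at 0
#' and attenuation 1 this is the identity.
#'
#' @param S matrix of clean spectra (samples x wavelengths).
#' @param state one of `"in_shell"`, `"de_shelled"`, `"granules"`.
#' @param cfg a [generator_config()].
#' @return matrix of the same shape.
#' @export
apply_state_effects <- function(S, state, cfg = generator_config()) {
  p <- cfg$state_params[[state]]
  if (is.null(p)) abort(sprintf("No state_params entry for state \"%s\".", state))
  w <- config_wavelengths(cfg)
  stopifnot(ncol(S) == length(w))
  n <- nrow(S)
  a <- rnorm(n, 1, p$scatter_sd)
  b <- rnorm(n, 0, p$offset_sd)
  d <- rnorm(n, 0, p$slope_sd)
  noise <- matrix(rnorm(n * length(w), 0, p$noise_sd), n)
  a * (p$attenuation * S) + b + outer(d, w - mean(range(w))) + p$level_shift + noise
}

#' Plant spectral and chemical outliers into a dataset
#'
#' Mirrors the two outlier classes of the screening stage: spectral outliers
#' (acquisition artifacts) receive a localized spurious Gaussian band of
#' amplitude `spectral_magnitude` centred at 1575 nm plus a mild
#' multiplicative distortion, so they are not a pure affine transform that
#' scatter correction would undo; chemical outliers (reference-assay errors)
#' have their `fat_percent` shifted by `+/- chemical_magnitude` with random
#' sign. Sampled ids are disjoint; non-outlier rows are untouched.
#'
#' @param data a `nir_dataset`.
#' @param cfg a [generator_config()].
#' @return list with elements `data` (corrupted dataset) and `truth`, a list
#'   with `spectral_ids`, `chemical_ids` and `clean_fat` (pre-corruption
#'   reference values).
#' @export
inject_outliers <- function(data, cfg = generator_config()) {
  validate_generator_config(cfg)
  n_s <- cfg$n_spectral_outliers
  n_c <- cfg$n_chemical_outliers
  truth <- list(spectral_ids = integer(0), chemical_ids = integer(0),
                clean_fat = data$fat_percent)
  if (n_s + n_c == 0) return(list(data = data, truth = truth))
  picked <- sample(data$sample_id, n_s + n_c)
  truth$spectral_ids <- sort(picked[seq_len(n_s)])
  truth$chemical_ids <- sort(picked[n_s + seq_len(n_c)])
  if (n_s > 0) {
    w <- dataset_wavelengths(data)
    artifact <- cfg$spectral_magnitude * exp(-(w - 1575)^2 / (2 * 12^2))
    X <- spectra_matrix(data)
    rows <- match(truth$spectral_ids, data$sample_id)
    X[rows, ] <- (1 + cfg$spectral_magnitude / 2) * X[rows, , drop = FALSE] +
      matrix(artifact, length(rows), length(w), byrow = TRUE)
    data <- set_spectra(data, X)
  }
  if (n_c > 0) {
    rows <- match(truth$chemical_ids, data$sample_id)
    signs <- sample(c(-1, 1), length(rows), replace = TRUE)
    data$fat_percent[rows] <- data$fat_percent[rows] + signs * cfg$chemical_magnitude
  }
  list(data = data, truth = truth)
}

#' Generate a complete synthetic dataset for one sample state
#'
#' Full generative pipeline: draw fat references from the truncated-normal
#' model, build clean spectra, simulate `replicate_count` state-affected
#' scans per sample and average them (emulating the triplicate-scan
#' protocol), then plant the configured outliers. Deterministic given
#' `seed`.
#'
#' @param cfg a [generator_config()].
#' @param state sample state label.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return list with `data` (a [nir_dataset()]) and `truth` (see
#'   [inject_outliers()]).
#' @export
#' @examples
#' g <- generate_dataset(generator_config(n_samples = 20), "granules", seed = 1)
#' dim(spectra_matrix(g$data))
generate_dataset <- function(cfg = generator_config(), state = "granules",
                             seed = cfg$seed) {
  validate_generator_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  fat <- sample_fat_values(n, cfg)
  clean <- synthesize_clean_spectrum(fat, cfg)
  acc <- matrix(0, n, ncol(clean))
  for (r in seq_len(cfg$replicate_count)) {
    acc <- acc + apply_state_effects(clean, state, cfg)
  }
  X <- acc / cfg$replicate_count
  data <- nir_dataset(X, config_wavelengths(cfg),
                      sample_ids = seq_len(n), fat = fat, state = state)
  inject_outliers(data, cfg)
}
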