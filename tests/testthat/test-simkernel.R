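test_that("Soxhlet formula reproduces gravimetric arithmetic and rejects bad masses", {
  expect_equal(soxhlet_fat(m0 = 100.0, m1 = 101.1, m = 2.0), 55.0)
  expect_equal(soxhlet_fat(m0 = 3, m1 = 3, m = 2.0), 0.0)
  expect_equal(soxhlet_fat(m0 = 50.0, m1 = 51.5086, m = 2.0), 75.43)
  expect_error(soxhlet_fat(100, 101, m = 0), "positive")
  expect_error(soxhlet_fat(100, 99, m = 2), "m0")
})

test_that("fat references follow the truncated-normal model", {
  cfg <- generator_config()
  set.seed(42)
  v <- sample_fat_values(210, cfg)
  expect_true(all(v >= cfg$fat_min & v <= cfg$fat_max))

  degenerate <- generator_config(fat_sd = 0)
  expect_equal(sample_fat_values(5, degenerate), rep(54.63, 5))

  # large-sample moments against a quadrature oracle on the truncated density
  set.seed(7)
  big <- sample_fat_values(10000, cfg)
  mom <- truncnorm_moments_oracle(cfg$fat_mean, cfg$fat_sd, cfg$fat_min, cfg$fat_max)
  expect_lt(abs(mean(big) - mom["mean"]), 0.5)
  expect_lt(abs(sd(big) - mom["sd"]), 0.5)
})

test_that("clean spectra have the configured band structure and are affine in fat", {
  cfg <- generator_config()
  w <- seq(cfg$wavelength_start, cfg$wavelength_stop, cfg$wavelength_step)

  flat <- generator_config(bands = data.frame(center = 1200, width = 40,
                                              fat_amp = 0, base_amp = 0))
  S <- synthesize_clean_spectrum(c(45, 60), flat)
  expect_equal(S[1, ], S[2, ])  # background only, no fat dependence

  S <- synthesize_clean_spectrum(54.63, cfg)
  win <- which(w >= 1150 & w <= 1250)
  expect_lte(abs(w[win][which.max(S[1, win])] - 1200), cfg$wavelength_step)

  # difference of two fats is proportional to the fat-coupled band shape
  S2 <- synthesize_clean_spectrum(c(45, 60, 75), cfg)
  d1 <- S2[2, ] - S2[1, ]
  d2 <- S2[3, ] - S2[2, ]
  expect_equal(d1 / 15, d2 / 15, tolerance = 1e-12)

  expect_error(synthesize_clean_spectrum(50, generator_config(bands = data.frame(
    center = numeric(0), width = numeric(0), fat_amp = numeric(0),
    base_amp = numeric(0)))), "band")
})

test_that("state effects reduce to identity when switched off", {
  cfg <- generator_config(state_params = list(
    granules = list(scatter_sd = 0, offset_sd = 0, slope_sd = 0,
                    attenuation = 1, noise_sd = 0, level_shift = 0)))
  S <- synthesize_clean_spectrum(c(45, 60), cfg)
  expect_equal(apply_state_effects(S, "granules", cfg), S)
  expect_error(apply_state_effects(S, "powder", cfg), "powder")
})

test_that("state effects reproduce the absorbance-level and noise orderings", {
  cfg <- generator_config()
  S <- synthesize_clean_spectrum(rep(54.63, 500), cfg)
  set.seed(99)
  lvl <- sapply(c("in_shell", "de_shelled", "granules"), function(st)
    mean(apply_state_effects(S, st, cfg)))
  expect_true(lvl["granules"] > lvl["de_shelled"])
  expect_true(lvl["de_shelled"] > lvl["in_shell"])

  one <- synthesize_clean_spectrum(54.63, cfg)
  noise <- sapply(c("in_shell", "de_shelled", "granules"), function(st) {
    reps <- t(sapply(1:500, function(i) apply_state_effects(one, st, cfg)[1, ]))
    mean(apply(reps, 2, sd))
  })
  expect_true(noise["in_shell"] > noise["de_shelled"])
  expect_true(noise["de_shelled"] > noise["granules"])
})

test_that("outlier injection records disjoint ground-truth ids and leaves clean rows alone", {
  cfg0 <- tiny_config(40)
  set.seed(5)
  g <- generate_dataset(cfg0, "granules", seed = 5)
  res <- inject_outliers(g$data, cfg0)
  expect_identical(res$data, g$data)
  expect_length(res$truth$spectral_ids, 0)
  expect_length(res$truth$chemical_ids, 0)

  cfg <- generator_config()  # plants 2 spectral + 3 chemical by default
  g2 <- generate_dataset(cfg, "granules", seed = 8)
  expect_length(unique(g2$truth$spectral_ids), 2)
  expect_length(unique(g2$truth$chemical_ids), 3)
  expect_length(intersect(g2$truth$spectral_ids, g2$truth$chemical_ids), 0)
  untouched <- setdiff(g2$data$sample_id, g2$truth$chemical_ids)
  rows <- match(untouched, g2$data$sample_id)
  expect_equal(g2$data$fat_percent[rows], g2$truth$clean_fat[rows])

  expect_error(generator_config(n_spectral_outliers = 1, spectral_magnitude = 0),
               "spectral_magnitude")
  expect_error(generator_config(n_samples = 3, n_spectral_outliers = 2,
                                n_chemical_outliers = 2), "outliers")
})

test_that("generated datasets have the design shape and are seed-reproducible", {
  cfg <- generator_config()
  g1 <- generate_dataset(cfg, "granules", seed = 3)
  expect_equal(dim(spectra_matrix(g1$data)), c(210, 651))
  expect_equal(g1$data$sample_id, 1:210)
  g2 <- generate_dataset(cfg, "granules", seed = 3)
  expect_identical(g1$data, g2$data)
  expect_identical(g1$truth, g2$truth)
})

test_that("triplicate averaging brings rows closer to the clean spectrum", {
  dev_for <- function(reps, seed) {
    cfg <- tiny_config(25, replicate_count = reps)
    g <- generate_dataset(cfg, "granules", seed = seed)
    set.seed(seed)
    fat <- sample_fat_values(25, cfg)
    clean <- synthesize_clean_spectrum(fat, cfg)
    sp <- cfg$state_params$granules
    expected <- sp$attenuation * clean + sp$level_shift
    mean(abs(spectra_matrix(g$data) - expected))
  }
  expect_lt(dev_for(3, 11), dev_for(1, 11))
  expect_lt(dev_for(3, 12), dev_for(1, 12))
})

test_that("averaging variance scales as 1/k", {
  cfg <- generator_config()
  one <- synthesize_clean_spectrum(54.63, cfg)
  sim_var <- function(k, n = 1500) {
    v <- replicate(n, {
      acc <- 0
      for (i in seq_len(k)) acc <- acc + apply_state_effects(one, "granules", cfg)[1, 50]
      acc / k
    })
    var(v)
  }
  set.seed(21)
  v1 <- sim_var(1)
  v3 <- sim_var(3)
  expect_equal(v3, v1 / 3, tolerance = 0.15)
})
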