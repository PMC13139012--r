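Package: nirfat
Title: Portable Near-Infrared Calibration Pipeline for Kernel Fat Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for quantifying fat in tree-nut kernels
    from portable near-infrared (NIR) spectra, covering three physical sample
    states (in-shell kernels, de-shelled kernels, kernel granules). Provides a
    synthetic-spectra generator emulating the fat-band phenomenology of
    Torreya grandis kernels, spectral pretreatment operators (Savitzky-Golay
    smoothing and derivatives, SNV, MSC, vector normalization, linear
    baseline detrending), PCA-Mahalanobis and concentration-residual outlier
    screening, SPXY calibration/prediction partitioning, NIPALS partial least
    squares regression with cross-validated latent-variable selection, and
    the standard evaluation metrics (R2, RMSE, RPD, RER).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
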