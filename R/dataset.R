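#' Spectral dataset container
#'
#' A `nir_dataset` is a wide tibble holding one averaged NIR spectrum per row
#' together with its metadata: the reserved columns `sample_id` (unique
#' integers), `state` (one of `"in_shell"`, `"de_shelled"`, `"granules"`,
#' `"unknown"`) and `fat_percent` (the Soxhlet reference value in % w/w, `NA`
#' for prediction-only data), followed by one absorbance column (AU) per
#' wavelength, named by the wavelength in nm (`"1000"`, `"1001"`, ...).
#' The wavelength grid must be strictly increasing and all absorbances finite.
#'
#' @param absorbance numeric matrix, samples in rows, wavelengths in columns
#'   (absorbance units).
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, one per column of `absorbance`.
#' @param sample_ids integer vector of unique sample identifiers.
#' @param fat optional numeric vector of reference fat values (% w/w).
#' @param state a single state label.
#'
#' @return A tibble of class `nir_dataset`.
#' @export
#' @examples
#' d <- nir_dataset(matrix(runif(6), 2), wavelengths = c(1000, 1001, 1002))
#' dataset_wavelengths(d)
nir_dataset <- function(absorbance, wavelengths,
                        sample_ids = seq_len(nrow(absorbance)),
                        fat = NULL, state = "unknown") {
  absorbance <- as.matrix(absorbance)
  n <- nrow(absorbance)
  if (length(wavelengths) != ncol(absorbance)) {
    abort("`wavelengths` must have one entry per absorbance column.")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("Wavelength grid must be strictly increasing.")
  }
  if (is.null(fat)) fat <- rep(NA_real_, n)
  out <- tibble(
    sample_id = as.integer(sample_ids),
    state = as.character(state),
    fat_percent = as.numeric(fat)
  )
  spec <- as_tibble(absorbance, .name_repair = "minimal")
  names(spec) <- format_wavelength(wavelengths)
  out <- dplyr::bind_cols(out, spec)
  out <- structure(out, class = c("nir_dataset", class(tibble())))
  validate_nir_dataset(out)
  out
}

meta_columns <- c("sample_id", "state", "fat_percent")
known_states <- c("in_shell", "de_shelled", "granules", "unknown")

format_wavelength <- function(w) {
  # fixed formatting so write -> read round-trips on the column names
  ifelse(w == round(w), sprintf("%d", as.integer(round(w))), sprintf("%g", w))
}

#' Validate a spectral dataset
#'
#' Checks the `nir_dataset` invariants: reserved metadata columns present,
#' strictly increasing numeric wavelength grid, unique sample ids, and no
#' non-finite absorbance values. Called by the constructor and the readers;
#' exported so externally assembled tibbles can be checked too.
#'
#' @param data a `nir_dataset` (or any tibble with the same layout).
#' @return `data`, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_nir_dataset <- function(data) {
  missing_meta <- setdiff(meta_columns, names(data))
  if (length(missing_meta) > 0) {
    abort(paste0("Missing reserved column(s): ", paste(missing_meta, collapse = ", ")))
  }
  w <- dataset_wavelengths(data)
  if (length(w) < 1) abort("Dataset has no wavelength columns.")
  if (anyNA(w)) abort("Non-numeric wavelength column name found.")
  if (any(diff(w) <= 0)) {
    bad <- which(diff(w) <= 0)[1]
    abort(sprintf(
      "Wavelength grid must be strictly increasing; violation between columns %s and %s.",
      format_wavelength(w[bad]), format_wavelength(w[bad + 1])
    ))
  }
  ids <- data$sample_id
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate sample_id: %s.", ids[anyDuplicated(ids)]))
  }
  X <- spectra_matrix(data)
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite absorbance at sample_id %s, wavelength %s nm.",
                  ids[bad[1]], format_wavelength(w[bad[2]])))
  }
  if (!all(data$state %in% known_states)) {
    abort(sprintf("Unknown state label \"%s\".",
                  setdiff(unique(data$state), known_states)[1]))
  }
  invisible(data)
}

#' Extract the wavelength grid (nm) of a dataset
#' @param data a `nir_dataset`.
#' @return numeric vector of wavelengths in nm.
#' @export
dataset_wavelengths <- function(data) {
  cols <- setdiff(names(data), meta_columns)
  suppressWarnings(as.numeric(cols))
}

#' Extract the absorbance matrix of a dataset
#' @param data a `nir_dataset`.
#' @return numeric matrix (samples x wavelengths), rownames = sample ids.
#' @export
spectra_matrix <- function(data) {
  cols <- setdiff(names(data), meta_columns)
  X <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(data$sample_id)
  X
}

#' Replace the absorbance matrix of a dataset
#' @param data a `nir_dataset`.
#' @param X replacement matrix, same dimensions as `spectra_matrix(data)`.
#' @return the dataset with new absorbances.
#' @export
set_spectra <- function(data, X) {
  cols <- setdiff(names(data), meta_columns)
  stopifnot(nrow(X) == nrow(data), ncol(X) == length(cols))
  data[, cols] <- as_tibble(as.matrix(X), .name_repair = "minimal")
  data
}

#' Read a wide-format spectral CSV
#'
#' Canonical interchange format: comma-separated UTF-8 with `.` decimal and
#' header `sample_id,state,fat_percent,<wavelength1>,<wavelength2>,...` where
#' wavelength headers are numbers in nm. A missing `fat_percent` column is
#' read as all-`NA` reference values.
#'
#' @param path file to read.
#' @return a validated [nir_dataset()].
#' @export
read_csv_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"fat_percent" %in% names(raw)) {
    raw$fat_percent <- NA_real_
  }
  if (!"state" %in% names(raw)) raw$state <- "unknown"
  missing_meta <- setdiff(meta_columns, names(raw))
  if (length(missing_meta) > 0) {
    abort(paste0("Missing reserved column(s): ", paste(missing_meta, collapse = ", ")))
  }
  wcols <- setdiff(names(raw), meta_columns)
  w <- suppressWarnings(as.numeric(wcols))
  if (anyNA(w)) {
    abort(sprintf("Column \"%s\" is neither a reserved column nor a numeric wavelength.",
                  wcols[which(is.na(w))[1]]))
  }
  for (col in wcols) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("Non-numeric absorbance in column %s, data row %d.", col, bad_row))
    }
  }
  out <- raw[, c(meta_columns, wcols)]
  out <- structure(as_tibble(out), class = c("nir_dataset", class(tibble())))
  validate_nir_dataset(out)
  out
}

#' Write a spectral dataset to CSV
#'
#' One row per sample, absorbances written with 6 decimal places and
#' reference values with 4, so a write/read round trip is stable at the
#' documented precision. If every reference value is `NA` the `fat_percent`
#' column is omitted.
#'
#' @param data a `nir_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(data, path) {
  validate_nir_dataset(data)
  w <- dataset_wavelengths(data)
  out <- data
  out[setdiff(names(out), meta_columns)] <-
    lapply(out[setdiff(names(out), meta_columns)], function(v) sprintf("%.6f", v))
  if (all(is.na(out$fat_percent))) {
    out$fat_percent <- NULL
  } else {
    out$fat_percent <- sprintf("%.4f", data$fat_percent)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Parses the `##XYDATA=(X++(Y..Y))` labelled-data record of a JCAMP-DX file
#' with plain AFFN (free-form numeric) values, applying `##XFACTOR` and
#' `##YFACTOR` scaling and checking the decoded length against `##NPOINTS`.
#' This covers the common single-spectrum export of portable NIR instruments;
#' compressed (SQZ/DIF/DUP) encodings and compound files are out of scope.
#'
#' @param path file to read.
#' @return a tibble with columns `wavelength` (nm) and `absorbance` (AU).
#' @export
read_jcampdx <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  get_record <- function(label) {
    hit <- grep(paste0("^##", label, "="), lines, value = TRUE)
    if (length(hit) == 0) abort(sprintf("Missing required record ##%s=.", label))
    sub(paste0("^##", label, "="), "", hit[1])
  }
  firstx <- as.numeric(get_record("FIRSTX"))
  lastx <- as.numeric(get_record("LASTX"))
  npoints <- as.integer(as.numeric(get_record("NPOINTS")))
  xfactor <- as.numeric(get_record("XFACTOR"))
  yfactor <- as.numeric(get_record("YFACTOR"))
  if (anyNA(c(firstx, lastx, npoints, xfactor, yfactor))) {
    abort("Non-numeric value in a required JCAMP-DX record.")
  }
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (length(start) == 0) abort("Missing ##XYDATA=(X++(Y..Y)) record.")
  end <- grep("^##", lines)
  end <- end[end > start[1]]
  body <- lines[(start[1] + 1):(if (length(end)) end[1] - 1 else length(lines))]
  ys <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (anyNA(vals)) abort(sprintf("Non-numeric token in XYDATA line: \"%s\"", ln))
    ys <- c(ys, vals[-1] * yfactor)  # first token per line is the X start value
  }
  if (length(ys) != npoints) {
    abort(sprintf("NPOINTS mismatch: header says %d, decoded %d values.",
                  npoints, length(ys)))
  }
  x <- seq(firstx, lastx, length.out = npoints) * xfactor
  tibble(wavelength = x, absorbance = ys)
}

#' @export
print.nir_dataset <- function(x, ...) {
  w <- dataset_wavelengths(x)
  cat(sprintf("<nir_dataset> %d samples x %d wavelengths (%g-%g nm), state(s): %s\n",
              nrow(x), length(w), min(w), max(w),
              paste(unique(x$state), collapse = ", ")))
  NextMethod()
}
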