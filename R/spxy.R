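#' Joint x-y distance matrix
#'
#' The SPXY distance: pairwise Euclidean distances on the spectra and
#' absolute differences on the reference values, each normalized by its
#' maximum, then summed, so spectral and concentration dissimilarity
#' contribute equally. Entries lie in `[0, 2]` with zero diagonal.
#'
#' @param X spectra matrix (samples x wavelengths).
#' @param y reference values, one per row.
#' @return symmetric n x n distance matrix.
#' @export
joint_distance_matrix <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  dx <- unname(as.matrix(stats::dist(X)))
  dy <- abs(outer(unname(y), unname(y), "-"))
  if (max(dx) == 0) abort("All spectra identical: spectral distances degenerate.")
  if (max(dy) == 0) abort("All reference values identical: y distances degenerate.")
  dx / max(dx) + dy / max(dy)
}

#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint x-y distances: a Kennard-Stone
#' style greedy max-min selection on [joint_distance_matrix()]. The pair at
#' maximum joint distance seeds the calibration set; samples are then added
#' one at a time, each the one whose minimum distance to the already
#' selected set is largest, until `floor(fraction * n)` are selected. The
#' remainder forms the prediction set. Deterministic; ties break to the
#' smallest sample id.
#'
#' @param data a `nir_dataset` with reference values (or a spectra matrix,
#'   in which case `y` must be given).
#' @param fraction calibration fraction in (0, 1); default 0.75 (the 3:1
#'   calibration : prediction ratio).
#' @param y reference values when `data` is a matrix.
#' @return a list of class `spxy_split` with `calibration_ids`,
#'   `prediction_ids`, `calibration_fraction` and `distance_definition`.
#' @export
#' @examples
#' g <- generate_dataset(generator_config(n_samples = 16), "granules", seed = 3)
#' sp <- spxy_split(g$data)
#' length(sp$calibration_ids)
spxy_split <- function(data, fraction = 0.75, y = NULL) {
  if (inherits(data, "nir_dataset")) {
    X <- spectra_matrix(data)
    y <- data$fat_percent
    ids <- data$sample_id
  } else {
    X <- as.matrix(data)
    ids <- seq_len(nrow(X))
  }
  n <- nrow(X)
  stopifnot(n >= 4, fraction > 0, fraction < 1, !is.null(y))
  n_cal <- floor(fraction * n)
  D <- joint_distance_matrix(X, y)
  sel <- spxy_select(D, n_cal)
  structure(list(
    calibration_ids = sort(ids[sel]),
    prediction_ids = sort(ids[-sel]),
    calibration_fraction = fraction,
    distance_definition = "dx/max(dx) + dy/max(dy)"
  ), class = "spxy_split")
}

# greedy max-min selection on a precomputed distance matrix; returns row
# indices in selection order. Ties break to the smallest index.
spxy_select <- function(D, n_cal) {
  n <- nrow(D)
  stopifnot(n_cal >= 2, n_cal <= n)
  # seed: the pair attaining the maximum distance (smallest indices on ties)
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1, ])
  min_dist <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    min_dist[sel] <- -Inf
    nxt <- which.max(min_dist)       # which.max returns the first (smallest id) tie
    sel <- c(sel, nxt)
    min_dist <- pmin(min_dist, D[, nxt])
  }
  sel
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> %d calibration / %d prediction (fraction %.2f)\n",
              length(x$calibration_ids), length(x$prediction_ids),
              x$calibration_fraction))
  invisible(x)
}

#' Serialize a split to JSON
#' @param split an [spxy_split()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
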