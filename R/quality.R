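#' Linear measurement error model
#'
#' Impedance magnitude errors follow `delta|Z| = a|Z| + b` and phase errors
#' `delta(phi) = c|phi| + d`. The relative phase term uses the phase
#' magnitude so the error is always a nonnegative magnitude. `b` is an
#' absolute impedance error in Ohm when applied to transfer impedances; the
#' same model weights complex resistivity spectra, where `b` acts in Ohm m.
#'
#' @param a relative magnitude error (dimensionless, default 0.02).
#' @param b absolute magnitude error (Ohm, default 0.01).
#' @param c_rel relative phase error (dimensionless, default 0.02).
#' @param d_abs absolute phase error in radians (default 0.001, i.e. 1 mrad).
#' @return an `error_model` list.
#' @export
error_model <- function(a = 0.02, b = 0.01, c_rel = 0.02, d_abs = 0.001) {
  vals <- c(a = a, b = b, c_rel = c_rel, d_abs = d_abs)
  if (any(vals < 0)) stop("error-model parameters must be >= 0")
  structure(as.list(vals), class = "error_model")
}

#' @rdname error_model
#' @param em an `error_model`.
#' @param z_mag impedance (or resistivity) magnitude, >= 0.
#' @return predicted magnitude error, same units as `z_mag`.
#' @export
magnitude_error <- function(em, z_mag) {
  if (any(z_mag < 0)) stop("magnitude must be >= 0")
  em$a * z_mag + em$b
}

#' @rdname error_model
#' @param phi phase in radians (sign irrelevant).
#' @return predicted absolute phase error in radians.
#' @export
phase_error <- function(em, phi) {
  em$c_rel * abs(phi) + em$d_abs
}

#' Data-driven absolute phase error
#'
#' The absolute phase error for one measurement frequency, set to half the
#' sample standard deviation of the valid phase readings at that frequency.
#'
#' @param phases phase values in radians at one frequency (NAs = invalid).
#' @return `d_abs` in radians.
#' @export
phase_error_from_data <- function(phases) {
  phases <- phases[is.finite(phases)]
  if (length(phases) < 2L)
    stop("need at least 2 valid phase values to estimate the phase error")
  0.5 * stats::sd(phases)
}

#' Multi-frequency impedance dataset with validity mask
#'
#' Complex transfer impedances per (configuration, frequency) plus a logical
#' mask; masked-out entries are excluded from all statistics and from the
#' inversion-ready export. Filters only ever shrink the valid set.
#'
#' @param scheme a `measurement_scheme` (see [enumerate_scheme()]).
#' @param freq_grid a [frequency_grid()].
#' @param z complex matrix, configurations x frequencies.
#' @param mask logical matrix, same shape; TRUE = valid. Default all valid.
#' @return an `impedance_dataset`.
#' @export
impedance_dataset <- function(scheme, freq_grid, z, mask = NULL) {
  z <- as.matrix(z)
  nf <- length(unclass(freq_grid))
  if (nrow(z) != nrow(scheme$configs) || ncol(z) != nf)
    stop("z must be (n_configs x n_frequencies)")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(z), ncol(z))
  if (!is.logical(mask) || !all(dim(mask) == dim(z)))
    stop("mask must be a logical matrix matching z")
  structure(list(scheme = scheme, freq_grid = freq_grid, z = z, mask = mask),
            class = "impedance_dataset")
}

#' @export
print.impedance_dataset <- function(x, ...) {
  cat(sprintf("<impedance_dataset> %d configs x %d frequencies, %d/%d valid\n",
              nrow(x$z), ncol(x$z), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Remove strongly positive (inductive) phase readings
#'
#' Capacitive polarization gives negative impedance phases; readings with a
#' phase above `+threshold` are physically implausible at these frequencies
#' and are masked out, per frequency. Negative phases are always retained.
#'
#' @param dataset an [impedance_dataset()].
#' @param threshold_rad positive-phase cutoff in radians
#'   (default 0.005 = 5 mrad).
#' @return the dataset with an updated mask.
#' @export
filter_positive_phase <- function(dataset, threshold_rad = 0.005) {
  if (threshold_rad < 0) stop("threshold must be >= 0")
  bad <- Arg(dataset$z) > threshold_rad
  dataset$mask <- dataset$mask & !bad
  dataset
}

#' Remove per-frequency phase outliers (k-sigma rule)
#'
#' For each frequency, in a single pass, the mean and sample standard
#' deviation of the currently valid impedance phases are computed and
#' entries deviating from the mean by more than `k` standard deviations are
#' masked out. The pass is not iterated.
#'
#' @param dataset an [impedance_dataset()].
#' @param k deviation multiple (default 3).
#' @return the dataset with an updated mask.
#' @export
filter_phase_ksigma <- function(dataset, k = 3) {
  ph <- Arg(dataset$z)
  for (j in seq_len(ncol(ph))) {
    valid <- dataset$mask[, j]
    if (sum(valid) < 3L) {
      warning(sprintf("frequency column %d: fewer than 3 valid entries, k-sigma filter skipped", j))
      next
    }
    mu <- mean(ph[valid, j])
    s <- stats::sd(ph[valid, j])
    if (s == 0) next
    out <- valid & (abs(ph[, j] - mu) > k * s)
    dataset$mask[, j] <- valid & !out
  }
  dataset
}

#' Standard raw-data filter chain
#'
#' Applies the positive-phase cutoff first, then the k-sigma outlier
#' removal, the pipeline's default order.
#'
#' @inheritParams filter_positive_phase
#' @inheritParams filter_phase_ksigma
#' @return the filtered dataset.
#' @export
filter_raw_data <- function(dataset, threshold_rad = 0.005, k = 3) {
  filter_phase_ksigma(filter_positive_phase(dataset, threshold_rad), k)
}
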