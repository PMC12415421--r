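#' Frequency grid for spectral measurements
#'
#' A strictly increasing vector of measurement frequencies in Hz. Spectral
#' induced polarization surveys typically sample frequencies log-evenly over
#' several decades; [default_frequency_grid()] reproduces the 23-point
#' 0.1 Hz - 10 kHz acquisition grid used throughout the package.
#'
#' @param frequencies numeric vector of frequencies in Hz; strictly
#'   increasing, all positive, length >= 2.
#' @return an object of class `frequency_grid` (a numeric vector).
#' @export
frequency_grid <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 2L)
    stop("frequency grid needs at least 2 frequencies")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and > 0")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  structure(frequencies, class = "frequency_grid")
}

#' @rdname frequency_grid
#' @param n number of log-evenly spaced points.
#' @param f_min,f_max band limits in Hz.
#' @export
default_frequency_grid <- function(n = 23L, f_min = 0.1, f_max = 1e4) {
  frequency_grid(10^seq(log10(f_min), log10(f_max), length.out = n))
}

#' Complex resistivity spectrum of one tomogram cell
#'
#' Magnitude-phase representation of the frequency-dependent complex
#' resistivity rho(omega). Phase is stored in radians; the capacitive
#' (normal induced-polarization) response has negative phase. All file I/O
#' uses mrad, the field's display unit; conversion happens at the I/O layer.
#'
#' @param grid a [frequency_grid()].
#' @param magnitude |rho| in Ohm m, one value per frequency, all > 0.
#' @param phase_rad resistivity phase in radians, |phase| < pi/2.
#' @return an object of class `complex_spectrum`.
#' @export
complex_spectrum <- function(grid, magnitude, phase_rad) {
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  magnitude <- as.numeric(magnitude)
  phase_rad <- as.numeric(phase_rad)
  nf <- length(unclass(grid))
  if (length(magnitude) != nf || length(phase_rad) != nf)
    stop("magnitude and phase must have one value per grid frequency")
  if (any(!is.finite(magnitude)) || any(magnitude <= 0))
    stop("magnitude must be finite and > 0 everywhere")
  if (any(!is.finite(phase_rad)) || any(abs(phase_rad) >= pi / 2))
    stop("|phase| must be < pi/2 rad")
  structure(list(grid = grid, magnitude = magnitude, phase_rad = phase_rad),
            class = "complex_spectrum")
}

#' @export
print.complex_spectrum <- function(x, ...) {
  f <- unclass(x$grid)
  cat(sprintf("<complex_spectrum> %d frequencies %.4g-%.4g Hz, |rho| %.4g-%.4g Ohm m, phase %.2f..%.2f mrad\n",
              length(f), min(f), max(f), min(x$magnitude), max(x$magnitude),
              1000 * min(x$phase_rad), 1000 * max(x$phase_rad)))
  invisible(x)
}

#' Complex resistivity values of a spectrum
#'
#' @param s a [complex_spectrum()].
#' @return complex vector rho(omega) = |rho| exp(i phase) per grid frequency.
#' @export
as_complex_resistivity <- function(s) {
  s$magnitude * exp(1i * s$phase_rad)
}

#' Convert complex resistivity to conductivity components
#'
#' Inverts the complex resistivity, sigma = 1/rho = sigma' + i sigma''.
#' The real part sigma' carries the conduction, the imaginary part sigma''
#' the polarization properties of the medium; for a capacitive response
#' (negative resistivity phase) sigma'' is positive.
#'
#' @param s a [complex_spectrum()].
#' @param f frequency in Hz; must be a grid member (see [value_at()] for
#'   interpolation).
#' @return named list with `sigma_re` and `sigma_im` in S/m.
#' @export
to_conductivity <- function(s, f) {
  idx <- match_grid_frequency(s$grid, f)
  sig <- 1 / (s$magnitude[idx] * exp(1i * s$phase_rad[idx]))
  list(sigma_re = Re(sig), sigma_im = Im(sig))
}

match_grid_frequency <- function(grid, f, rel_tol = 1e-9) {
  g <- unclass(grid)
  idx <- which(abs(g - f) <= rel_tol * f)
  if (length(idx) != 1L) {
    below <- g[g < f]
    above <- g[g > f]
    stop(sprintf(
      "frequency %g Hz not on grid; nearest grid frequencies: %s Hz",
      f, paste(signif(c(if (length(below)) max(below), if (length(above)) min(above)), 6),
               collapse = " and ")))
  }
  idx
}

#' Resolve a complex resistivity value at an arbitrary frequency
#'
#' `mode = "exact"` requires `f` to be a grid member. `mode = "loglog"`
#' interpolates the log-magnitude and the phase linearly in log-frequency,
#' appropriate for log-evenly sampled spectra. Frequencies outside the grid
#' span are never extrapolated.
#'
#' @param s a [complex_spectrum()].
#' @param f frequency in Hz within the grid span.
#' @param mode `"loglog"` (default) or `"exact"`.
#' @return complex resistivity at `f` in Ohm m.
#' @export
value_at <- function(s, f, mode = c("loglog", "exact")) {
  mode <- match.arg(mode)
  g <- unclass(s$grid)
  if (f < min(g) || f > max(g))
    stop(sprintf("frequency %g Hz outside grid span [%g, %g] Hz; refusing to extrapolate",
                 f, min(g), max(g)))
  if (mode == "exact") {
    idx <- match_grid_frequency(s$grid, f)
    return(s$magnitude[idx] * exp(1i * s$phase_rad[idx]))
  }
  lf <- log(g)
  mag <- exp(stats::approx(lf, log(s$magnitude), xout = log(f))$y)
  ph  <- stats::approx(lf, s$phase_rad, xout = log(f))$y
  mag * exp(1i * ph)
}

#' 2D tomogram cell grid
#'
#' Cell centers along the profile (x, positive right) and depth (z, positive
#' down) with per-cell volumes. Profile inversions are per unit out-of-plane
#' length, so a cell's volume is its in-plane area times 1 m thickness.
#'
#' @param cell_id unique cell identifiers.
#' @param x,z cell center coordinates in m.
#' @param volume_m3 cell volumes in m^3, all > 0.
#' @return a `cell_grid` data.frame.
#' @export
cell_grid <- function(cell_id, x, z, volume_m3) {
  if (anyDuplicated(cell_id)) stop("cell_ids must be unique")
  if (any(volume_m3 <= 0)) stop("cell volumes must be > 0")
  df <- data.frame(cell_id = cell_id, x = as.numeric(x), z = as.numeric(z),
                   volume_m3 = as.numeric(volume_m3), stringsAsFactors = FALSE)
  class(df) <- c("cell_grid", "data.frame")
  df
}

#' Build a regular 2D cell grid
#'
#' @param x_length profile length in m.
#' @param depth profile depth in m.
#' @param dx,dz cell sizes in m.
#' @return a [cell_grid()] with row-major cell ids `c<row>_<col>`.
#' @export
regular_cell_grid <- function(x_length, depth, dx = 0.05, dz = 0.05) {
  xs <- seq(dx / 2, x_length - dx / 2, by = dx)
  zs <- seq(dz / 2, depth - dz / 2, by = dz)
  gg <- expand.grid(x = xs, z = zs, KEEP.OUT.ATTRS = FALSE)
  cell_grid(cell_id = sprintf("c%03d_%03d",
                              match(gg$z, zs), match(gg$x, xs)),
            x = gg$x, z = gg$z, volume_m3 = dx * dz * 1)
}

#' Stack of per-cell spectra on a tomogram grid
#'
#' The pipeline's central container: every cell of a 2D grid carries one
#' complex resistivity spectrum, all sharing a single frequency grid.
#' Internally the spectra are stored as cell-by-frequency matrices of
#' magnitude and phase for vectorized access.
#'
#' @param grid a [cell_grid()].
#' @param freq_grid a [frequency_grid()] shared by all cells.
#' @param magnitude numeric matrix (cells x frequencies) of |rho| in Ohm m.
#' @param phase_rad numeric matrix (cells x frequencies) of phase in radians.
#' @return an object of class `tomogram_stack`.
#' @export
tomogram_stack <- function(grid, freq_grid, magnitude, phase_rad) {
  stopifnot(inherits(grid, "cell_grid"))
  if (!inherits(freq_grid, "frequency_grid")) freq_grid <- frequency_grid(freq_grid)
  magnitude <- as.matrix(magnitude)
  phase_rad <- as.matrix(phase_rad)
  nf <- length(unclass(freq_grid))
  if (nrow(magnitude) != nrow(grid) || ncol(magnitude) != nf ||
      !all(dim(phase_rad) == dim(magnitude)))
    stop("magnitude/phase must be (n_cells x n_frequencies) matrices")
  if (any(magnitude <= 0)) stop("magnitudes must be > 0")
  if (any(abs(phase_rad) >= pi / 2)) stop("|phase| must be < pi/2 rad")
  structure(list(grid = grid, freq_grid = freq_grid,
                 magnitude = magnitude, phase_rad = phase_rad),
            class = "tomogram_stack")
}

#' @export
print.tomogram_stack <- function(x, ...) {
  f <- unclass(x$freq_grid)
  cat(sprintf("<tomogram_stack> %d cells x %d frequencies (%.3g-%.3g Hz)\n",
              nrow(x$grid), length(f), min(f), max(f)))
  invisible(x)
}

#' Extract one cell's spectrum from a stack
#'
#' @param stack a [tomogram_stack()].
#' @param cell_id the cell to extract.
#' @return a [complex_spectrum()].
#' @export
cell_spectrum <- function(stack, cell_id) {
  i <- match(cell_id, stack$grid$cell_id)
  if (is.na(i)) stop(sprintf("unknown cell_id '%s'", cell_id))
  complex_spectrum(stack$freq_grid, stack$magnitude[i, ], stack$phase_rad[i, ])
}

#' Volume-weighted mean spectrum over a set of cells
#'
#' Averages complex resistivity (real and imaginary parts) across cells,
#' weighted by cell volume, and returns the result in magnitude-phase form.
#'
#' @param stack a [tomogram_stack()].
#' @param cell_ids member cells.
#' @return a [complex_spectrum()].
#' @export
mean_spectrum <- function(stack, cell_ids) {
  idx <- match(cell_ids, stack$grid$cell_id)
  if (anyNA(idx)) stop("unknown cell_ids in mean_spectrum")
  w <- stack$grid$volume_m3[idx]
  w <- w / sum(w)
  rho <- stack$magnitude[idx, , drop = FALSE] *
    exp(1i * stack$phase_rad[idx, , drop = FALSE])
  m <- colSums(w * rho)
  complex_spectrum(stack$freq_grid, Mod(m), Arg(m))
}
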