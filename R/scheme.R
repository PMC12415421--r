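#' Surface electrode array
#'
#' Electrode positions on the surface line of a profile. Four-point
#' measurement schemes (current dipole A-B, potential dipole M-N) are
#' built on top of this array.
#'
#' @param x electrode x positions in m along the profile.
#' @param z electrode depths in m (default 0: surface line).
#' @return an `electrode_array` data.frame with 1-based electrode numbers.
#' @export
electrode_array <- function(x, z = 0) {
  x <- as.numeric(x)
  z <- rep_len(as.numeric(z), length(x))
  if (length(x) < 4L) stop("an array needs at least 4 electrodes")
  if (anyDuplicated(cbind(x, z))) stop("electrode positions must be distinct")
  df <- data.frame(electrode = seq_along(x), x = x, z = z)
  class(df) <- c("electrode_array", "data.frame")
  df
}

#' Geometric factor of a four-point configuration
#'
#' For point electrodes on a homogeneous half-space the transfer impedance
#' is Z = rho / K with
#' K = 2 pi / (1/r_AM - 1/r_AN - 1/r_BM + 1/r_BN),
#' where r are inter-electrode distances. The sign of K carries the dipole
#' orientation; magnitude-based scheme filters use |K|.
#'
#' @param array an [electrode_array()].
#' @param a,b,m,n 1-based electrode indices, all distinct.
#' @return K in m.
#' @export
geometric_factor <- function(array, a, b, m, n) {
  idx <- c(a, b, m, n)
  if (anyDuplicated(idx)) stop("electrodes A, B, M, N must be distinct")
  if (any(idx < 1L | idx > nrow(array))) stop("electrode index out of range")
  p <- array[, c("x", "z")]
  r <- function(i, j) sqrt((p$x[i] - p$x[j])^2 + (p$z[i] - p$z[j])^2)
  denom <- 1 / r(a, m) - 1 / r(a, n) - 1 / r(b, m) + 1 / r(b, n)
  if (abs(denom) < .Machine$double.eps)
    stop("degenerate geometry: geometric-factor denominator is zero")
  2 * pi / denom
}

#' Four-point impedance from three-point potentials
#'
#' Multichannel impedance tomographs record the potential of every
#' electrode against a common reference during each current injection;
#' arbitrary four-point transfer impedances follow by superposition:
#' Z = (U_M - U_N) / I.
#'
#' @param u_m,u_n complex potentials of M and N against the reference, in V.
#' @param i_ab complex injected current in A, nonzero.
#' @return complex transfer impedance in Ohm.
#' @export
superpose_three_point <- function(u_m, u_n, i_ab) {
  if (all(Mod(i_ab) == 0)) stop("injected current must be nonzero")
  (as.complex(u_m) - as.complex(u_n)) / as.complex(i_ab)
}

#' Enumerate a four-point measurement scheme
#'
#' For each current injection (A, B), in acquisition order, all unordered
#' potential dipoles \{M, N\} disjoint from \{A, B\} are generated (stored
#' with M < N; the sign of K carries orientation), then filtered by:
#' * maximum absolute geometric factor `max_abs_k` (small |K| configurations
#'   have high signal-to-noise ratio);
#' * optionally, removal of configurations whose M or N served as a current
#'   electrode in the immediately preceding injection, to avoid residual
#'   electrode-polarization effects.
#'
#' @param array an [electrode_array()].
#' @param injections two-column matrix or data.frame of (A, B) pairs in
#'   acquisition order.
#' @param max_abs_k maximum |K| in m (default 5; `Inf` disables).
#' @param exclude_previous_injection drop configs reusing the previous
#'   injection's current electrodes as potential electrodes (default TRUE).
#' @return a `measurement_scheme` list with `array`, `injections` and a
#'   `configs` data.frame (columns a, b, m, n, k_m) in deterministic order
#'   (injection order, then m, then n ascending).
#' @export
enumerate_scheme <- function(array, injections, max_abs_k = 5,
                             exclude_previous_injection = TRUE) {
  injections <- as.matrix(injections)
  if (ncol(injections) != 2L) stop("injections must have two columns (A, B)")
  storage.mode(injections) <- "integer"
  n_el <- nrow(array)
  out <- vector("list", nrow(injections))
  for (i in seq_len(nrow(injections))) {
    ab <- injections[i, ]
    if (ab[1] == ab[2]) stop("injection with coincident electrodes")
    pot <- setdiff(seq_len(n_el), ab)
    if (length(pot) < 2L) next
    dip <- t(utils::combn(sort(pot), 2L))   # m < n, ascending order
    if (exclude_previous_injection && i > 1L) {
      prev <- injections[i - 1L, ]
      keep <- !(dip[, 1] %in% prev | dip[, 2] %in% prev)
      dip <- dip[keep, , drop = FALSE]
    }
    if (nrow(dip) == 0L) next
    k <- vapply(seq_len(nrow(dip)), function(j)
      geometric_factor(array, ab[1], ab[2], dip[j, 1], dip[j, 2]), numeric(1))
    keep <- abs(k) <= max_abs_k
    if (!any(keep)) next
    out[[i]] <- data.frame(a = ab[1], b = ab[2],
                           m = dip[keep, 1], n = dip[keep, 2],
                           k_m = k[keep])
  }
  configs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(configs)) {
    warning("scheme is empty after filtering")
    configs <- data.frame(a = integer(), b = integer(), m = integer(),
                          n = integer(), k_m = numeric())
  }
  rownames(configs) <- NULL
  structure(list(array = array, injections = injections, configs = configs),
            class = "measurement_scheme")
}

#' @export
print.measurement_scheme <- function(x, ...) {
  cat(sprintf("<measurement_scheme> %d electrodes, %d injections, %d configurations\n",
              nrow(x$array), nrow(x$injections), nrow(x$configs)))
  invisible(x)
}

#' Write / read a measurement scheme as a text table
#'
#' Plain whitespace-delimited text with a header line; columns
#' `a b m n k_m`.
#'
#' @param scheme a `measurement_scheme`.
#' @param path output file.
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(scheme$configs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
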