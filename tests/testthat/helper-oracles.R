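# Independent oracles and fixture builders used across the suite.

# Geometric factor evaluated from first principles (independent of
# geometric_factor): explicit distance formula, explicit sum.
oracle_k <- function(pos, a, b, m, n) {
  d <- function(i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))
  2 * pi / (1 / d(a, m) - 1 / d(a, n) - 1 / d(b, m) + 1 / d(b, n))
}

# Brute-force scheme enumeration: nested loops applying the three rules
# (dipole disjoint from injection, |K| cap, previous-injection exclusion)
# one configuration at a time.
oracle_scheme <- function(pos, injections, max_abs_k, exclude_prev) {
  rows <- list()
  n_el <- nrow(pos)
  for (i in seq_len(nrow(injections))) {
    a <- injections[i, 1]; b <- injections[i, 2]
    for (m in seq_len(n_el - 1L)) for (n in (m + 1L):n_el) {
      if (m %in% c(a, b) || n %in% c(a, b)) next
      if (exclude_prev && i > 1L) {
        prev <- injections[i - 1L, ]
        if (m %in% prev || n %in% prev) next
      }
      k <- oracle_k(pos, a, b, m, n)
      if (abs(k) > max_abs_k) next
      rows[[length(rows) + 1L]] <- data.frame(a = a, b = b, m = m, n = n,
                                              k_m = k)
    }
  }
  if (!length(rows))
    return(data.frame(a = integer(), b = integer(), m = integer(),
                      n = integer(), k_m = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Brute-force composed filter: positive-phase cutoff then one-pass k-sigma,
# column by column, entry by entry.
oracle_filter <- function(ph, mask, thr, k) {
  for (j in seq_len(ncol(ph))) {
    for (i in seq_len(nrow(ph)))
      if (mask[i, j] && ph[i, j] > thr) mask[i, j] <- FALSE
    valid <- which(mask[, j])
    if (length(valid) >= 3L) {
      mu <- mean(ph[valid, j]); s <- sd(ph[valid, j])
      if (s > 0)
        for (i in valid)
          if (abs(ph[i, j] - mu) > k * s) mask[i, j] <- FALSE
    }
  }
  mask
}

# Noise-free spectrum of a Debye superposition on a frequency grid.
debye_spectrum <- function(rho0, m, tau, grid = default_frequency_grid()) {
  rho <- debye_forward(rho0, m, tau, unclass(grid))
  complex_spectrum(grid, Mod(rho), Arg(rho))
}

# Error-model Gaussian noise applied to a spectrum (the scene generator's
# noise recipe, rebuilt here so generator tests stay independent).
noisy_spectrum <- function(sp, em) {
  mag <- sp$magnitude + rnorm(length(sp$magnitude), 0,
                              magnitude_error(em, sp$magnitude))
  ph <- sp$phase_rad + rnorm(length(sp$phase_rad), 0,
                             phase_error(em, sp$phase_rad))
  complex_spectrum(sp$grid, pmax(mag, 0.05 * sp$magnitude), ph)
}

# Small impedance dataset over a 6-electrode line with random complex Z.
random_impedance_dataset <- function(n_freq = 4) {
  arr <- electrode_array(seq(0, by = 0.5, length.out = 6))
  sch <- enumerate_scheme(arr, rbind(c(1, 2), c(5, 6)), max_abs_k = Inf,
                          exclude_previous_injection = FALSE)
  nc <- nrow(sch$configs)
  ph <- matrix(rnorm(nc * n_freq, mean = -0.01, sd = 0.01), nc, n_freq)
  z <- matrix(rlnorm(nc * n_freq, 2, 0.3), nc, n_freq) * exp(1i * ph)
  impedance_dataset(sch, frequency_grid(10^seq(0, 3, length.out = n_freq)), z)
}
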