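test_that("the Debye forward model matches hand-evaluated cases", {
  f <- c(0.1, 1, 10, 100, 1000)
  # no polarization: flat real spectrum
  expect_equal(debye_forward(100, 0, 1, f), rep(100 + 0i, 5))
  # high-frequency limit of a single term: rho0 (1 - m)
  hf <- debye_forward(100, 0.1, 0.05, 1e9)
  expect_equal(Re(hf), 90, tolerance = 1e-6)
  # omega tau = 1: rho = rho0 (1 - m (1+i)/2)
  f1 <- 1 / (2 * pi * 0.05)
  z <- debye_forward(100, 0.1, 0.05, f1)
  expect_equal(z, 100 * (0.95 - 0.05i), tolerance = 1e-12)
  expect_equal(Arg(z) * 1000, -52.58, tolerance = 1e-3)
  expect_error(debye_forward(100, c(0.6, 0.5), c(1, 2), f), "sum\\(m\\) < 1")
})

test_that("noise-free single-term spectra are recovered accurately", {
  sp <- debye_spectrum(100, 0.05, 0.05)
  fit <- fit_debye(sp)
  expect_lt(abs(fit$m_tot / 0.05 - 1), 0.02)
  expect_lt(abs(fit$tau_mean / 0.05 - 1), 0.05)
  expect_gt(fit$rho0, 0)
  expect_true(all(fit$m >= 0))
  expect_lt(sum(fit$m), 1)
})

test_that("forward/inverse round trip with on-grid tau reaches machine misfit", {
  grid <- default_frequency_grid()
  tg <- default_tau_grid(0.1, 1e4)
  tau_on <- as.numeric(tg)[abs(log10(as.numeric(tg) / 0.05)) ==
                             min(abs(log10(as.numeric(tg) / 0.05)))][1]
  sp <- debye_spectrum(100, 0.05, tau_on, grid)
  fit <- fit_debye(sp, tau_grid = tg)
  expect_lt(fit$rms, 1e-6)
  expect_lt(abs(fit$m_tot - 0.05), 1e-3)
  expect_equal(fit$tau_mean, tau_on, tolerance = 1e-3)
})

test_that("flat spectra fit to negligible chargeability", {
  sp <- complex_spectrum(default_frequency_grid(), rep(80, 23), rep(0, 23))
  fit <- fit_debye(sp)
  expect_lt(fit$m_tot, 1e-4)
  expect_true(is.na(fit$tau_mean) || fit$m_tot < 1e-4)
})

test_that("two-term spectra recover total chargeability and mean time scale", {
  sp <- debye_spectrum(100, c(0.03, 0.03), c(0.005, 0.2))
  fit <- fit_debye(sp)
  expect_lt(abs(fit$m_tot / 0.06 - 1), 0.05)
  expect_lt(abs(fit$tau_mean / sqrt(0.005 * 0.2) - 1), 0.15)
})

test_that("integral parameters follow their definitions", {
  fit <- structure(list(m = c(0.01, 0.02, 0.03), tau = c(1e-3, 1e-2, 1e-1)),
                   class = "debye_fit")
  expect_equal(total_chargeability(fit), 0.06)
  fit0 <- structure(list(m = rep(0, 3), tau = c(1e-3, 1e-2, 1e-1)),
                    class = "debye_fit")
  expect_equal(total_chargeability(fit0), 0)
  expect_true(is.na(mean_relaxation_time(fit0)))
  # single active node
  fit1 <- structure(list(m = c(0, 0.04, 0), tau = c(0.01, 0.05, 0.1)),
                    class = "debye_fit")
  expect_equal(mean_relaxation_time(fit1), 0.05)
  # equal weights: geometric mean
  fit2 <- structure(list(m = c(0.02, 0.02), tau = c(0.01, 0.1)),
                    class = "debye_fit")
  expect_equal(mean_relaxation_time(fit2), sqrt(0.001), tolerance = 1e-12)
  # weighted case, hand-evaluated
  fit3 <- structure(list(m = c(0.3, 0.1), tau = c(0.01, 0.1)),
                    class = "debye_fit")
  expect_equal(mean_relaxation_time(fit3),
               exp((0.3 * log(0.01) + 0.1 * log(0.1)) / 0.4),
               tolerance = 1e-12)
})

test_that("restricted decomposition isolates the low-frequency process", {
  # unrestricted equals the plain fit when f_max covers the grid
  sp <- debye_spectrum(100, 0.05, 0.05)
  expect_equal(fit_debye_restricted(sp, Inf)$m,
               fit_debye(sp)$m)
  # bimodal spectrum: the <= 55 Hz fit recovers the slow relaxation
  spb <- debye_spectrum(100, c(0.05, 0.05), c(0.05, 2e-4))
  rfit <- fit_debye_restricted(spb, 55)
  expect_lt(abs(rfit$tau_mean / 0.05 - 1), 0.20)
  expect_lt(rfit$f_max_used, 55 + 1e-9)
  # too few low frequencies
  expect_error(fit_debye_restricted(spb, 0.2), ">= 4 frequencies")
})

test_that("fit guards degenerate inputs", {
  g <- frequency_grid(c(1, 10, 100))
  expect_error(fit_debye(complex_spectrum(g, rep(100, 3), rep(-0.01, 3))),
               ">= 4")
  sp_pos <- complex_spectrum(default_frequency_grid(), rep(100, 23),
                             rep(0.005, 23))
  expect_warning(fit <- fit_debye(sp_pos), "inductive")
  expect_lt(fit$m_tot, 1e-3)
})

test_that("adding a positive term never decreases fitted total chargeability", {
  set.seed(23)
  for (rep in 1:50) {
    m1 <- runif(1, 0.01, 0.06)
    t1 <- 10^runif(1, -3, 0)
    m2 <- runif(1, 0.005, 0.05)
    t2 <- 10^runif(1, -3, 0)
    f1 <- fit_debye(debye_spectrum(100, m1, t1))
    f2 <- fit_debye(debye_spectrum(100, c(m1, m2), c(t1, t2)))
    expect_gte(f2$m_tot, f1$m_tot - 1e-4)
  }
})

test_that("phase extremum frequency is the inverse of the relaxation time", {
  grid <- default_frequency_grid()
  f <- unclass(grid)
  step <- log10(f[2] / f[1])
  for (tau in c(0.002, 0.02, 0.2)) {
    sp <- debye_spectrum(100, 0.05, tau, grid)
    f_peak <- f[which.min(sp$phase_rad)]
    expect_lt(abs(log10(f_peak) - log10(1 / (2 * pi * tau))), step + 1e-9)
  }
})

test_that("the gram-matrix NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(5)
  for (rep in 1:10) {
    A <- matrix(rnorm(40 * 12), 40, 12)
    b <- A %*% runif(12) + rnorm(40, 0, 0.1)
    got <- rootsip:::nnls_gram(crossprod(A), as.vector(crossprod(A, b)))
    want <- pracma::lsqnonneg(A, as.vector(b))$x
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("recovery under the field error model is approximately unbiased", {
  em <- error_model(a = 0.02, b = 0.01, c_rel = 0.02, d_abs = 0.001)
  sp0 <- debye_spectrum(100, 0.05, 0.05)
  set.seed(101)
  fits <- replicate(200, {
    f <- fit_debye(noisy_spectrum(sp0, em), em = em)
    c(f$m_tot, f$tau_mean)
  })
  expect_lt(abs(mean(fits[1, ]) / 0.05 - 1), 0.10)
  expect_lt(abs(mean(fits[2, ]) / 0.05 - 1), 0.20)
})
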