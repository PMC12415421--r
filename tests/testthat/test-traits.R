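test_that("root-zone selection counts cell centers in the closed window", {
  grid <- regular_cell_grid(4, 1, dx = 0.05, dz = 0.05)
  zone <- select_zone(grid, stem_x = 2.0)    # [1.9, 2.1] x [0, 0.25]
  expect_equal(length(zone$cell_ids), 4L * 5L)
  expect_equal(zone$v_rz, 20 * 0.05 * 0.05)
  expect_error(select_zone(grid, stem_x = 10), "no cell centers")
  # center exactly on the window boundary is included
  g2 <- cell_grid(c("a", "b", "c"), c(1.9, 2.1, 2.2), c(0.25, 0.1, 0.1),
                  rep(1e-3, 3))
  z2 <- select_zone(g2, 2.0)
  expect_setequal(z2$cell_ids, c("a", "b"))
})

test_that("soil reference zone selects the 50-100 cm depth band", {
  grid <- regular_cell_grid(1, 1.2, dx = 0.1, dz = 0.1)
  zone <- soil_reference_zone(grid)
  expect_true(all(grid$z[match(zone$cell_ids, grid$cell_id)] >= 0.5))
  expect_true(all(grid$z[match(zone$cell_ids, grid$cell_id)] <= 1.0))
  expect_equal(length(zone$cell_ids), 10L * 5L)
  expect_error(soil_reference_zone(grid, z_range = c(5, 6)), "no cell centers")
})

test_that("zone means are volume-weighted with renormalized exclusions", {
  grid <- cell_grid(c("a", "b"), c(0, 0.1), c(0.1, 0.1), c(1, 3))
  zone <- list(cell_ids = c("a", "b"), v_rz = 4)
  class(zone) <- "root_zone"
  expect_equal(zone_weighted_mean(c(a = 1, b = 3), zone, grid), 2.5)
  # equal volumes reduce to the arithmetic mean
  ge <- cell_grid(c("a", "b"), c(0, 0.1), c(0.1, 0.1), c(2, 2))
  expect_equal(zone_weighted_mean(c(a = 1, b = 3), zone, ge), 2)
  # all-equal values return that value regardless of volumes
  expect_equal(zone_weighted_mean(c(a = 7, b = 7), zone, grid), 7)
  # single cell
  z1 <- structure(list(cell_ids = "a", v_rz = 1), class = "root_zone")
  expect_equal(zone_weighted_mean(c(a = 42), z1, grid), 42)
  # flagged cells are dropped and the volume renormalized
  expect_warning(m <- zone_weighted_mean(c(a = 1, b = NA), zone, grid),
                 "renormalized")
  expect_equal(m, 1)
})

test_that("ERI follows the log-log dispersion definition", {
  # flat imaginary conductivity: zero dispersion
  expect_equal(eri(1e-4, 1e-4), 0)
  # frozen substitution case at the standard frequency bounds
  expect_equal(eri(1e-4, 1e-3), log10(10) / log10(320), tolerance = 1e-12)
  # invariance under multiplicative scaling of sigma''
  set.seed(9)
  s_lf <- rlnorm(50, -9, 1); s_hf <- s_lf * rlnorm(50, 0.5, 0.3)
  gain <- rlnorm(50, 0, 1)   # e.g. a depth-dependent sensitivity field
  expect_equal(eri(gain * s_lf, gain * s_hf), eri(s_lf, s_hf),
               tolerance = 1e-12)
  # log-base invariance
  expect_equal(eri(s_lf, s_hf),
               log10(s_hf / s_lf) / log10(1000 / 3.125), tolerance = 1e-12)
  # nonpositive imaginary parts are flagged, not computed
  expect_true(is.na(eri(0, 1e-3)))
  expect_true(is.na(eri(-1e-5, 1e-3)))
  expect_error(eri(1e-4, 1e-3, f_lf = 10, f_hf = 10), "f_hf > f_lf")
})

test_that("phase-approximation ERI matches the definition for gentle spectra", {
  expect_equal(eri_phase_approx(-0.005, -0.005), 0)
  expect_equal(eri_phase_approx(-0.005, -0.020),
               log(4) / log(320), tolerance = 1e-12)
  expect_true(is.na(eri_phase_approx(0.004, -0.004)))
  expect_true(is.na(eri_phase_approx(0, -0.004)))
  # |sigma| varying < 1 % and |phi| <= 25 mrad: agreement with eri() to < 1 %
  set.seed(21)
  for (rep in 1:20) {
    mag_lf <- 60
    mag_hf <- mag_lf * runif(1, 0.995, 1.005)
    ph_lf <- -runif(1, 0.002, 0.005)
    ph_hf <- ph_lf * runif(1, 3.5, 5)     # clear dispersion, |phi| <= 25 mrad
    s_lf <- Im(1 / (mag_lf * exp(1i * ph_lf)))
    s_hf <- Im(1 / (mag_hf * exp(1i * ph_hf)))
    e1 <- eri(s_lf, s_hf)
    e2 <- eri_phase_approx(ph_lf, ph_hf)
    expect_lt(abs(e2 - e1) / abs(e1), 0.01)
  }
})

test_that("the per-cell ERI field flags invalid cells and sees root anomalies", {
  # homogeneous single-term field: spatially constant ERI
  grid <- regular_cell_grid(0.4, 0.2, dx = 0.1, dz = 0.1)
  fg <- default_frequency_grid()
  rho <- debye_forward(100, 0.04, 1e-3, unclass(fg))
  st <- tomogram_stack(grid, fg,
                       matrix(Mod(rho), nrow(grid), 23, byrow = TRUE),
                       matrix(Arg(rho), nrow(grid), 23, byrow = TRUE))
  field <- eri_map(st)
  expect_equal(unname(diff(range(field))), 0, tolerance = 1e-12)
  # a cell with nonpositive sigma'' at the low frequency is flagged
  st$phase_rad[2, ] <- abs(st$phase_rad[2, ])   # inductive cell
  f2 <- eri_map(st)
  expect_true(is.na(f2[2]))
  expect_false(anyNA(f2[-2]))
})

test_that("maize-zone ERI exceeds the soil ERI in a synthetic scene", {
  scene <- build_scene(scene_preset("t2", seed = 2))
  field <- eri_map(scene$stack)
  grid <- scene$stack$grid
  soil <- soil_reference_zone(grid)
  soil_eri <- zone_weighted_mean(field, soil, grid)
  mz <- scene$plants[scene$plants$species == "maize", ]
  for (i in seq_len(nrow(mz))) {
    z <- select_zone(grid, mz$stem_x[i])
    expect_gt(zone_weighted_mean(field, z, grid), soil_eri)
  }
})

test_that("Schwarz relation translates relaxation times to diameters", {
  # 50 ms at D = 1e-9 m^2/s: exactly 20 micrometres
  expect_equal(schwarz_diameter(0.050), 20e-6)
  expect_equal(schwarz_diameter(0), 0)
  # printed-value convention: truncation to integer micrometres
  expect_equal(schwarz_diameter_um(0.017), 11)
  expect_equal(schwarz_diameter_um(0.050), 20)
  expect_equal(schwarz_diameter_um(0.080), 25)
  # strictly increasing and exactly invertible via tau = d^2 / (8 D)
  taus <- 10^seq(-4, 0, length.out = 30)
  d <- schwarz_diameter(taus)
  expect_true(all(diff(d) > 0))
  expect_equal(d^2 / (8 * 1e-9), taus, tolerance = 1e-12)
})

test_that("root biomass density is mass over zone volume", {
  expect_equal(rbd(0.05, 0.01), 5)
  expect_equal(rbd(0, 0.01), 0)
  # the excavation volume of a 20 x 20 x 25 cm pit
  expect_equal(0.20 * 0.20 * 0.25, 0.01)
  zone <- structure(list(cell_ids = "a", v_rz = 0.01), class = "root_zone")
  expect_equal(rbd(0.05, zone), 5)
  expect_error(rbd(0.05, 0), "> 0")
})

test_that("pearson wraps the t-distribution correlation test", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$pc, 1)
  expect_equal(pearson(x, -x)$pc, -1)
  p <- pearson(x, c(1, 3, 2, 5))
  expect_equal(p$pc, 0.8315218, tolerance = 1e-6)
  expect_equal(p$p_value, cor.test(x, c(1, 3, 2, 5))$p.value)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(c(1, 2), c(1, 2)), "at least 3")
})
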