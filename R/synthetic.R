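#' Synthetic field scene configuration
#'
#' Describes a ground-truth 2D profile: a homogeneous soil background with a
#' broad polarization spectrum, plus per-plant anomalies that add species-
#' typical Debye terms inside the root zone. Spectra are generated with the
#' Debye forward model on the acquisition frequency grid and perturbed with
#' Gaussian noise whose standard deviations follow the linear magnitude and
#' phase error models.
#'
#' @param x_length,depth,dx,dz grid geometry in m.
#' @param freq_grid acquisition [frequency_grid()].
#' @param soil list: `rho0` (Ohm m) and `terms`, a list of `c(m, tau)`
#'   Debye terms.
#' @param plants list of per-plant anomalies: each a list with `species`,
#'   `stem_x` (m), `terms` (list of `c(m, tau)` added inside the zone),
#'   optional `depth` (zone depth, default 0.25 m).
#' @param coupling list linking true high-frequency chargeability to fresh
#'   root biomass: `gain` (kg per unit chargeability per m^3), `intercept`
#'   (kg), `sigma` (lognormal noise sd). `NULL` for no validation table.
#' @param em [error_model()] for the added noise, or `NULL` for noise-free.
#' @param zone_width root-zone width in m (default 0.20).
#' @param seed RNG seed; a fixed seed makes the scene fully reproducible.
#' @return a `scene_config` list.
#' @export
scene_config <- function(x_length = 9.75, depth = 1.0, dx = 0.05, dz = 0.05,
                         freq_grid = default_frequency_grid(),
                         soil = soil_model(),
                         plants = list(),
                         coupling = list(gain = 50, intercept = 0, sigma = 0.25),
                         em = error_model(),
                         zone_width = 0.20,
                         seed = 1L) {
  for (p in plants) {
    tot <- sum(vapply(soil$terms, `[`, numeric(1), 1)) +
      sum(vapply(p$terms, `[`, numeric(1), 1))
    if (tot >= 1)
      stop("total chargeability (soil + anomaly) must stay < 1 in every cell")
  }
  structure(list(x_length = x_length, depth = depth, dx = dx, dz = dz,
                 freq_grid = freq_grid, soil = soil, plants = plants,
                 coupling = coupling, em = em, zone_width = zone_width,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default soil polarization model
#'
#' A broad high-frequency dispersion: phase decreases monotonically with
#' frequency to about -10 mrad at 1 kHz, with mild low-frequency
#' polarization of a few mrad, emulating a silty field soil.
#'
#' @param rho0 DC resistivity in Ohm m.
#' @return list with `rho0` and Debye `terms`.
#' @export
soil_model <- function(rho0 = 60) {
  list(rho0 = rho0,
       terms = list(c(0.004, 0.3),      # ~0.5 Hz, few-mrad LF background
                    c(0.005, 0.02),     # ~8 Hz
                    c(0.008, 0.002),    # ~80 Hz
                    c(0.016, 1.5e-4),   # ~1 kHz, dominant HF dispersion
                    c(0.016, 1.5e-5)))  # ~10 kHz tail
}

#' Species anomaly presets
#'
#' Debye terms added inside a plant's root zone. Maize: a high-frequency
#' (>= 100 Hz) dispersion strengthening the phase to about -15 mrad;
#' `strength` scales the added chargeability (range about 0.01-0.04 across
#' plants). Sugar beet: a strong high-frequency polarization (to about
#' -25 mrad at 1 kHz) plus a low-frequency storage-tissue peak at
#' relaxation time `tau_low` (17-80 ms over the season, peak -10 to
#' -15 mrad).
#'
#' @param strength added high-frequency chargeability (maize).
#' @return list of `c(m, tau)` terms.
#' @export
maize_anomaly <- function(strength = 0.02) {
  list(c(strength, 1.5e-4), c(strength / 2, 1.5e-5))
}

#' @rdname maize_anomaly
#' @param tau_low low-frequency relaxation time in s (storage tissue).
#' @param m_low chargeability of the low-frequency term.
#' @param m_high added high-frequency chargeability.
#' @export
beet_anomaly <- function(tau_low = 0.05, m_low = 0.05, m_high = 0.025) {
  list(c(m_low, tau_low), c(m_high, 1.5e-4), c(m_high / 2, 1.5e-5))
}

#' Seasonal scene presets
#'
#' Three snapshot configurations emulating early (`t1`), mid (`t2`) and
#' late (`t3`) season: the sugar-beet low-frequency relaxation time grows
#' 17 -> 50 -> 80 ms with increasing low-frequency chargeability, while
#' eight maize plants carry high-frequency anomalies of graded strength.
#'
#' @param timestep `"t1"`, `"t2"` or `"t3"`.
#' @param seed RNG seed passed to the scene.
#' @param em error model for noise (default the standard field settings).
#' @return a [scene_config()].
#' @export
scene_preset <- function(timestep = c("t2", "t1", "t3"), seed = 1L,
                         em = error_model()) {
  timestep <- match.arg(timestep)
  beet_par <- switch(timestep,
    t1 = list(tau_low = 0.017, m_low = 0.012),
    t2 = list(tau_low = 0.050, m_low = 0.025),
    t3 = list(tau_low = 0.080, m_low = 0.030))
  maize_strength <- seq(0.010, 0.035, length.out = 8)
  plants <- c(
    lapply(seq_len(8), function(i)
      list(species = "maize", stem_x = 0.7 + i * 0.75,
           terms = maize_anomaly(maize_strength[i]))),
    list(list(species = "sugar_beet", stem_x = 8.0,
              terms = do.call(beet_anomaly, beet_par)),
         list(species = "sugar_beet", stem_x = 8.8,
              terms = do.call(beet_anomaly,
                              c(beet_par["tau_low"],
                                list(m_low = beet_par$m_low * 0.8))))))
  scene_config(plants = plants, em = em, seed = seed)
}

#' Build a synthetic scene
#'
#' Composes per-cell Debye parameters (soil background plus species anomaly
#' inside each plant zone), evaluates the forward model on the acquisition
#' grid, adds error-model noise, and (if a coupling is configured) draws
#' linked fresh-root-mass validation records. Fully reproducible under the
#' config seed.
#'
#' @param config a [scene_config()].
#' @return a `synthetic_scene` list: `stack` (noisy [tomogram_stack()]),
#'   `truth` (per-cell data.frame: `cell_id`, `m_tot_true` (total
#'   chargeability), `m_hf_true` (root-attributable high-frequency
#'   chargeability, zero in unplanted soil), `plant_id`), `plants`
#'   ([plant_records()] with true RBD columns), and the `config`.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  grid <- regular_cell_grid(config$x_length, config$depth, config$dx, config$dz)
  f <- unclass(config$freq_grid)
  nf <- length(f)
  nc <- nrow(grid)

  term_mat <- function(terms) {
    m <- vapply(terms, `[`, numeric(1), 1)
    tau <- vapply(terms, `[`, numeric(1), 2)
    list(m = m, tau = tau)
  }
  # chargeability relaxing above ~100 Hz counts as high-frequency
  hf_part <- function(tm) sum(tm$m[tm$tau < 1 / (2 * pi * 100)])

  soil_tm <- term_mat(config$soil$terms)
  rho_groups <- list(soil = debye_forward(config$soil$rho0, soil_tm$m,
                                          soil_tm$tau, f))
  group_of <- rep("soil", nc)
  m_tot_true <- rep(sum(soil_tm$m), nc)
  m_hf_true <- rep(0, nc)   # soil carries no root-attributable chargeability
  plant_id <- rep(NA_character_, nc)

  plant_ids <- character(0)
  for (i in seq_along(config$plants)) {
    p <- config$plants[[i]]
    pid <- sprintf("%s_%02d", substr(p$species, 1, 1), i)
    plant_ids <- c(plant_ids, pid)
    ptm <- term_mat(p$terms)
    all_m <- c(soil_tm$m, ptm$m)
    all_tau <- c(soil_tm$tau, ptm$tau)
    rho_groups[[pid]] <- debye_forward(config$soil$rho0, all_m, all_tau, f)
    zdepth <- if (is.null(p$depth)) 0.25 else p$depth
    inz <- abs(grid$x - p$stem_x) <= config$zone_width / 2 & grid$z <= zdepth
    group_of[inz] <- pid
    m_tot_true[inz] <- sum(all_m)
    m_hf_true[inz] <- hf_part(ptm)   # root-attributable HF chargeability
    plant_id[inz] <- pid
  }

  rho <- do.call(rbind, rho_groups)[match(group_of, names(rho_groups)), ,
                                    drop = FALSE]
  mag <- Mod(rho)
  ph <- Arg(rho)
  if (!is.null(config$em)) {
    sd_mag <- magnitude_error(config$em, mag)
    sd_ph <- phase_error(config$em, ph)
    mag <- mag + matrix(stats::rnorm(nc * nf), nc, nf) * sd_mag
    mag <- pmax(mag, 0.05 * Mod(rho))   # keep magnitudes physical (> 0)
    ph <- ph + matrix(stats::rnorm(nc * nf), nc, nf) * sd_ph
  }
  stack <- tomogram_stack(grid, config$freq_grid, mag, ph)
  truth <- data.frame(cell_id = grid$cell_id, m_tot_true = m_tot_true,
                      m_hf_true = m_hf_true, plant_id = plant_id,
                      stringsAsFactors = FALSE)
  scene <- structure(list(stack = stack, truth = truth, plants = NULL,
                          config = config),
                     class = "synthetic_scene")
  if (!is.null(config$coupling) && length(config$plants) > 0)
    scene$plants <- attach_validation(scene, config$coupling)
  scene
}

#' Draw linked root-validation records for a scene
#'
#' Emulates the assumed monotone link between the (true) zone-mean
#' high-frequency chargeability and root biomass:
#' `mass = gain * mean(m_hf) * V_rz * exp(N(0, sigma)) + intercept`.
#' The noise-free truth (`rbd_true`) is stored alongside the noisy mass.
#'
#' @param scene a `synthetic_scene` (from [build_scene()]).
#' @param coupling list with `gain` (> 0), `intercept`, `sigma` (>= 0).
#' @return a [plant_records()] data.frame with extra columns `m_hf_zone`
#'   (true zone-mean high-frequency chargeability), `v_rz` and `rbd_true`.
#' @export
attach_validation <- function(scene, coupling = list(gain = 50, intercept = 0,
                                                     sigma = 0.25)) {
  config <- scene$config
  grid <- scene$stack$grid
  plants <- config$plants
  rows <- lapply(seq_along(plants), function(i) {
    p <- plants[[i]]
    pid <- sprintf("%s_%02d", substr(p$species, 1, 1), i)
    zdepth <- if (is.null(p$depth)) 0.25 else p$depth
    zone <- select_zone(grid, p$stem_x, width = config$zone_width,
                        depth = zdepth, plant_id = pid)
    vals <- stats::setNames(scene$truth$m_hf_true, scene$truth$cell_id)
    m_hf <- zone_weighted_mean(vals, zone, grid)
    noise <- if (coupling$sigma > 0) exp(stats::rnorm(1, 0, coupling$sigma)) else 1
    mass <- coupling$gain * m_hf * zone$v_rz * noise + coupling$intercept
    data.frame(plant_id = pid, species = p$species, stem_x = p$stem_x,
               fresh_root_mass_kg = mass, offset_flag = FALSE,
               m_hf_zone = m_hf, v_rz = zone$v_rz,
               rbd_true = coupling$gain * m_hf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("plant_records", "data.frame")
  out
}

#' Transfer impedances of a spectrum over a homogeneous half-space
#'
#' For a homogeneous half-space of complex resistivity rho(omega), every
#' four-point configuration measures `Z(omega) = rho(omega) / K`; the phase
#' of Z equals the phase of rho since K is real.
#'
#' @param spectrum a [complex_spectrum()] of the half-space.
#' @param scheme a `measurement_scheme` (see [enumerate_scheme()]).
#' @return an [impedance_dataset()].
#' @export
halfspace_impedances <- function(spectrum, scheme) {
  rho <- as_complex_resistivity(spectrum)
  z <- outer(1 / scheme$configs$k_m, rho)
  impedance_dataset(scheme, spectrum$grid, z)
}
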