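#' Read and write spectra tables
#'
#' The spectra table is plain comma-separated text, one row per
#' (cell, frequency), with mandatory header
#' `cell_id, x_m, z_m, volume_m3, frequency_hz, rho_mag_ohmm, phase_mrad`.
#' Phase is stored in mrad on disk (the field's display unit) and converted
#' to radians in memory. Rows may arrive with frequencies out of order; they
#' are sorted per cell. Validation failures report offending row numbers.
#'
#' @param path file path.
#' @return [read_spectra()]: a [tomogram_stack()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "x_m", "z_m", "volume_m3", "frequency_hz",
                "rho_mag_ohmm", "phase_mrad")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("spectra table missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$rho_mag_ohmm) | df$rho_mag_ohmm <= 0)
  if (length(bad))
    stop("non-positive resistivity magnitude at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  dup <- which(duplicated(df[, c("cell_id", "frequency_hz")]))
  if (length(dup))
    stop("duplicate (cell_id, frequency) at row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  df <- df[order(df$cell_id, df$frequency_hz), ]   # deterministic cell order
  freqs <- sort(unique(df$frequency_hz))
  cells <- unique(df[, c("cell_id", "x_m", "z_m", "volume_m3")])
  if (nrow(df) != nrow(cells) * length(freqs))
    stop("spectra table is not complete: every cell needs every frequency")
  grid <- cell_grid(cells$cell_id, cells$x_m, cells$z_m, cells$volume_m3)
  nf <- length(freqs)
  mag <- matrix(df$rho_mag_ohmm, nrow(cells), nf, byrow = TRUE)
  ph <- matrix(df$phase_mrad / 1000, nrow(cells), nf, byrow = TRUE)
  tomogram_stack(grid, frequency_grid(freqs), mag, ph)
}

#' @rdname read_spectra
#' @param stack a [tomogram_stack()].
#' @export
write_spectra <- function(stack, path) {
  g <- stack$grid
  f <- unclass(stack$freq_grid)
  df <- data.frame(
    cell_id = rep(g$cell_id, each = length(f)),
    x_m = rep(g$x, each = length(f)),
    z_m = rep(g$z, each = length(f)),
    volume_m3 = rep(g$volume_m3, each = length(f)),
    frequency_hz = rep(f, times = nrow(g)),
    rho_mag_ohmm = as.vector(t(stack$magnitude)),
    phase_mrad = as.vector(t(stack$phase_rad)) * 1000)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write plant tables
#'
#' Comma-separated text with header
#' `plant_id, species, x_m, fresh_root_mass_kg, offset_flag`.
#'
#' @param path file path.
#' @return [read_plants()]: a [plant_records()] data.frame.
#' @export
read_plants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plant_id", "species", "x_m", "fresh_root_mass_kg")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("plant table missing columns: ", paste(missing, collapse = ", "))
  if (is.null(df$offset_flag)) df$offset_flag <- FALSE
  plant_records(df$plant_id, df$species, df$x_m, df$fresh_root_mass_kg,
                as.logical(df$offset_flag))
}

#' @rdname read_plants
#' @param plants a [plant_records()] data.frame.
#' @export
write_plants <- function(plants, path) {
  df <- data.frame(plant_id = plants$plant_id, species = plants$species,
                   x_m = plants$stem_x,
                   fresh_root_mass_kg = plants$fresh_root_mass_kg,
                   offset_flag = plants$offset_flag)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis chain, with defaults matching the
#' standard field settings: ERI bounds 3.125 Hz and 1 kHz, full
#' decomposition capped at 1 kHz, restricted decomposition at 55 Hz,
#' positive-phase cutoff 5 mrad, 3-sigma outlier rule, error model
#' a = 2 %, b = 0.01, c = 2 %, d = 1 mrad, zone window 20 cm x 25 cm, soil
#' reference depth 0.5-1.0 m, diffusion coefficient 1e-9 m^2/s.
#'
#' @param spectra,plants input table paths (or NULL when a stack/records
#'   are passed to [run_pipeline()] directly).
#' @param f_lf,f_hf ERI frequency bounds in Hz.
#' @param f_max_fit upper bound of the full Debye decomposition in Hz.
#' @param f_max_restricted upper bound of the restricted decomposition.
#' @param zone_width,zone_depth root-zone window in m.
#' @param soil_z soil reference depth band in m.
#' @param positive_phase_mrad positive-phase filter threshold.
#' @param sigma_k k of the k-sigma phase filter.
#' @param error list of error-model parameters `a`, `b`, `c_rel`, `d_abs`.
#' @param diffusion ion diffusion coefficient in m^2/s.
#' @param seed RNG seed for any stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(spectra = NULL, plants = NULL,
                       f_lf = 3.125, f_hf = 1000,
                       f_max_fit = 1000, f_max_restricted = 55,
                       zone_width = 0.20, zone_depth = 0.25,
                       soil_z = c(0.50, 1.00),
                       positive_phase_mrad = 5, sigma_k = 3,
                       error = list(a = 0.02, b = 0.01, c_rel = 0.02,
                                    d_abs = 0.001),
                       diffusion = 1e-9, seed = 1L) {
  if (f_lf >= f_hf) stop("need f_lf < f_hf")
  if (zone_width <= 0 || zone_depth <= 0) stop("zone dimensions must be > 0")
  structure(list(spectra = spectra, plants = plants, f_lf = f_lf, f_hf = f_hf,
                 f_max_fit = f_max_fit, f_max_restricted = f_max_restricted,
                 zone_width = zone_width, zone_depth = zone_depth,
                 soil_z = soil_z, positive_phase_mrad = positive_phase_mrad,
                 sigma_k = sigma_k, error = error, diffusion = diffusion,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with a subset of the `run_config` fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Composes the chain in its standard order: load spectra and plant tables,
#' compute the per-cell ERI field, select per-plant root zones and the soil
#' reference zone, aggregate volume-weighted zone means, Debye-decompose
#' zone-mean spectra (full band for chargeability; restricted band for
#' sugar-beet relaxation times and Schwarz cell diameters), derive root
#' biomass densities, and correlate electrical with validation traits.
#'
#' @param config a [run_config()] (or path to its YAML form).
#' @param stack optional [tomogram_stack()] overriding `config$spectra`.
#' @param plants optional [plant_records()] overriding `config$plants`.
#' @param out_dir optional directory for the output tables.
#' @return a `pipeline_report` list: `traits` (per-plant table), `eri`
#'   (per-cell field), `soil` (reference-zone summary), `correlations`,
#'   `config_hash`, `log` (per-stage counts).
#' @export
run_pipeline <- function(config, stack = NULL, plants = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  logl <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (is.null(stack))
    stack <- stage("read_spectra", read_spectra(config$spectra))
  if (is.null(plants))
    plants <- stage("read_plants", read_plants(config$plants))
  logl$n_cells <- nrow(stack$grid)
  logl$n_plants <- nrow(plants)

  em <- do.call(error_model, config$error)
  eri_field <- stage("eri_map", eri_map(stack, config$f_lf, config$f_hf))
  logl$n_eri_invalid <- sum(!is.finite(eri_field))

  soil_zone <- stage("soil_zone",
                     soil_reference_zone(stack$grid, config$soil_z))
  soil_eri <- suppressWarnings(
    zone_weighted_mean(eri_field, soil_zone, stack$grid))
  soil_fit <- stage("soil_fit",
                    fit_debye(mean_spectrum(stack, soil_zone$cell_ids),
                              em = em, f_max = config$f_max_fit))

  rows <- lapply(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    zone <- select_zone(stack$grid, p$stem_x, config$zone_width,
                        config$zone_depth, plant_id = p$plant_id)
    sp <- mean_spectrum(stack, zone$cell_ids)
    fit <- fit_debye(sp, em = em, f_max = config$f_max_fit)
    mean_eri <- suppressWarnings(
      zone_weighted_mean(eri_field, zone, stack$grid))
    mean_rho <- Mod(value_at(sp, config$f_lf))
    tau_s <- NA_real_
    diam <- NA_real_
    if (p$species == "sugar_beet") {
      rfit <- fit_debye_restricted(sp, config$f_max_restricted, em = em)
      tau_s <- rfit$tau_mean
      diam <- schwarz_diameter(tau_s, config$diffusion)
    }
    data.frame(plant_id = p$plant_id, species = p$species, stem_x = p$stem_x,
               v_rz = zone$v_rz, mean_rho_mag = mean_rho,
               mean_m_tot = fit$m_tot, mean_tau_s = tau_s, mean_eri = mean_eri,
               rbd = p$fresh_root_mass_kg / zone$v_rz,
               cell_diameter_m = diam,
               cell_diameter_um = if (is.na(diam)) NA_real_ else trunc(diam * 1e6),
               stringsAsFactors = FALSE)
  })
  traits <- stage("traits", do.call(rbind, rows))

  correlations <- list()
  mz <- traits[traits$species == "maize" & is.finite(traits$mean_eri), ]
  if (nrow(mz) >= 3 && stats::sd(mz$rbd) > 0)
    correlations$maize_eri_rbd <- pearson(mz$mean_eri, mz$rbd)
  sb <- traits[traits$species == "sugar_beet", ]
  if (nrow(sb) >= 3 && stats::sd(sb$rbd) > 0) {
    correlations$beet_mtot_rbd <- pearson(sb$mean_m_tot, sb$rbd)
    correlations$beet_rho_rbd <- pearson(sb$mean_rho_mag, sb$rbd)
  }

  report <- structure(list(
    traits = traits,
    eri = eri_field,
    soil = list(mean_eri = soil_eri, m_tot = soil_fit$m_tot,
                n_cells = length(soil_zone$cell_ids)),
    correlations = correlations,
    config_hash = config_hash(config),
    log = logl
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tr <- traits
    tr$config_hash <- report$config_hash
    utils::write.csv(tr, file.path(out_dir, "traits.csv"), row.names = FALSE)
    eri_df <- data.frame(cell_id = names(eri_field), eri = unname(eri_field),
                         config_hash = report$config_hash)
    utils::write.csv(eri_df, file.path(out_dir, "eri_map.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d plants, %d cells (%d ERI-invalid), config %s\n",
              nrow(x$traits), x$log$n_cells, x$log$n_eri_invalid,
              substr(x$config_hash, 1, 8)))
  for (nm in names(x$correlations))
    cat(sprintf("  %s: PC = %.3f (p = %.3g)\n", nm,
                x$correlations[[nm]]$pc, x$correlations[[nm]]$p_value))
  invisible(x)
}

#' Write the tables of a synthetic scene
#'
#' Writes the spectra table, plant table and per-cell truth table of a
#' [build_scene()] result into a directory as plain CSV.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(scene$stack, file.path(dir, "spectra.csv"))
  if (!is.null(scene$plants))
    write_plants(scene$plants, file.path(dir, "plants.csv"))
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
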