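#' Plant validation records
#'
#' One row per excavated plant: species, stem position along the profile,
#' fresh root biomass from excavation ("shovelomics"), and whether the
#' plant sits off the image plane.
#'
#' @param plant_id unique identifiers.
#' @param species `"sugar_beet"` or `"maize"`.
#' @param stem_x stem positions in m along the profile.
#' @param fresh_root_mass_kg fresh root biomass in kg, >= 0.
#' @param offset_flag logical: plant off-centered perpendicular to the
#'   profile (default FALSE).
#' @return a `plant_records` data.frame.
#' @export
plant_records <- function(plant_id, species, stem_x, fresh_root_mass_kg,
                          offset_flag = FALSE) {
  species <- match.arg(species, c("sugar_beet", "maize"), several.ok = TRUE)
  if (any(fresh_root_mass_kg < 0)) stop("fresh root mass must be >= 0")
  df <- data.frame(plant_id = plant_id,
                   species = rep_len(species, length(plant_id)),
                   stem_x = as.numeric(stem_x),
                   fresh_root_mass_kg = as.numeric(fresh_root_mass_kg),
                   offset_flag = rep_len(as.logical(offset_flag), length(plant_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("plant_records", "data.frame")
  df
}

#' Root zone of a plant
#'
#' Cells whose centers fall inside the rectangular window
#' `x in [stem_x - width/2, stem_x + width/2]`, `z in [0, depth]`
#' (closed intervals), matching the excavated soil-root volume used for
#' validation (20 cm wide, 25 cm deep by default).
#'
#' @param grid a [cell_grid()].
#' @param stem_x stem position in m.
#' @param width,depth window dimensions in m.
#' @param plant_id identifier carried through to the result.
#' @return a `root_zone` list: `plant_id`, `cell_ids`, `v_rz` (m^3),
#'   window bounds.
#' @export
select_zone <- function(grid, stem_x, width = 0.20, depth = 0.25,
                        plant_id = NA_character_) {
  x_lo <- stem_x - width / 2
  x_hi <- stem_x + width / 2
  inside <- grid$x >= x_lo & grid$x <= x_hi & grid$z >= 0 & grid$z <= depth
  if (!any(inside))
    stop(sprintf("no cell centers inside window [%g, %g] x [0, %g]",
                 x_lo, x_hi, depth))
  structure(list(plant_id = plant_id,
                 cell_ids = grid$cell_id[inside],
                 v_rz = sum(grid$volume_m3[inside]),
                 x_range = c(x_lo, x_hi), z_range = c(0, depth)),
            class = "root_zone")
}

#' Root-free soil reference zone
#'
#' All cells in a depth band (50-100 cm by default), classified as mostly
#' root-free, optionally restricted to an x extent.
#'
#' @param grid a [cell_grid()].
#' @param z_range depth band in m (closed interval).
#' @param x_range optional profile extent in m (closed interval).
#' @return a `root_zone` with `plant_id = "soil"`.
#' @export
soil_reference_zone <- function(grid, z_range = c(0.50, 1.00),
                                x_range = NULL) {
  inside <- grid$z >= z_range[1] & grid$z <= z_range[2]
  if (!is.null(x_range))
    inside <- inside & grid$x >= x_range[1] & grid$x <= x_range[2]
  if (!any(inside)) stop("no cell centers inside the soil reference zone")
  structure(list(plant_id = "soil",
                 cell_ids = grid$cell_id[inside],
                 v_rz = sum(grid$volume_m3[inside]),
                 x_range = x_range, z_range = z_range),
            class = "root_zone")
}

#' Volume-weighted zone mean
#'
#' Mean of a per-cell quantity over a zone, weighted by cell volume:
#' `(1/V_rz) * sum(V_j * value_j)`. Cells with missing (NA) values are
#' excluded and the zone volume renormalized accordingly, with a warning.
#'
#' @param values named numeric vector (names = cell_ids), or a vector
#'   aligned with `grid$cell_id`.
#' @param zone a `root_zone`.
#' @param grid the [cell_grid()] the zone was built on.
#' @return the volume-weighted mean.
#' @export
zone_weighted_mean <- function(values, zone, grid) {
  idx <- match(zone$cell_ids, grid$cell_id)
  if (anyNA(idx)) stop("zone references cells missing from the grid")
  v <- grid$volume_m3[idx]
  val <- if (!is.null(names(values))) values[zone$cell_ids] else values[idx]
  ok <- is.finite(val)
  if (!any(ok)) stop("no valid cell values in zone")
  if (!all(ok)) {
    warning(sprintf("%d/%d zone cells flagged invalid; excluded with V_rz renormalized",
                    sum(!ok), length(ok)))
    v <- v[ok]; val <- val[ok]
  }
  sum(v * val) / sum(v)
}

#' Electrical root index (ERI)
#'
#' Log-log slope of the imaginary conductivity between a low and a high
#' frequency: `ERI = log(sigma''_HF / sigma''_LF) / log(f_HF / f_LF)`.
#' Normalizing the high-frequency (root plus soil) polarization with the
#' low-frequency (soil-dominated) polarization yields a spectral dispersion
#' measure primarily sensitive to root presence. The ratio form makes the
#' index invariant to the logarithm base and to any frequency-independent
#' multiplicative scaling of sigma''.
#'
#' @param sigma_lf,sigma_hf imaginary conductivities sigma'' in S/m at the
#'   low and high frequency; must be > 0, else the result is flagged NA
#'   (cells with imaginary parts close to zero at the low frequency are the
#'   known outlier mechanism).
#' @param f_lf,f_hf the two frequencies in Hz, `f_hf > f_lf`.
#' @return the ERI (dimensionless); NA where either sigma'' <= 0.
#' @export
eri <- function(sigma_lf, sigma_hf, f_lf = 3.125, f_hf = 1000) {
  if (f_hf <= f_lf) stop("need f_hf > f_lf")
  out <- rep(NA_real_, length(sigma_lf))
  ok <- is.finite(sigma_lf) & is.finite(sigma_hf) & sigma_lf > 0 & sigma_hf > 0
  out[ok] <- log(sigma_hf[ok] / sigma_lf[ok]) / log(f_hf / f_lf)
  out
}

#' ERI from resistivity phases (small-phase approximation)
#'
#' For small phases, sigma'' = |sigma| sin(|phi|) ~ |sigma| |phi|; if the
#' conductivity magnitude is about equal at the two frequencies the ERI
#' reduces to `log(phi_HF / phi_LF) / log(f_HF / f_LF)` on the phase
#' magnitudes. Flagged NA when either phase is zero or the signs differ.
#'
#' @param phi_lf,phi_hf resistivity phases in radians at the two
#'   frequencies (normally both negative).
#' @inheritParams eri
#' @return the approximate ERI; NA where invalid.
#' @export
eri_phase_approx <- function(phi_lf, phi_hf, f_lf = 3.125, f_hf = 1000) {
  if (f_hf <= f_lf) stop("need f_hf > f_lf")
  out <- rep(NA_real_, length(phi_lf))
  ok <- is.finite(phi_lf) & is.finite(phi_hf) &
    phi_lf != 0 & phi_hf != 0 & sign(phi_lf) == sign(phi_hf)
  out[ok] <- log(abs(phi_hf[ok]) / abs(phi_lf[ok])) / log(f_hf / f_lf)
  out
}

#' Per-cell ERI field of a tomogram stack
#'
#' Resolves the imaginary conductivity at the two index frequencies for
#' every cell (log-log interpolation when a frequency is not a grid member)
#' and computes the ERI. Cells with nonpositive sigma'' at either frequency
#' are flagged NA and later excluded from zone means.
#'
#' @param stack a [tomogram_stack()].
#' @inheritParams eri
#' @return named numeric vector of ERI values (names = cell_ids).
#' @export
eri_map <- function(stack, f_lf = 3.125, f_hf = 1000) {
  sig2 <- function(f) {
    g <- unclass(stack$freq_grid)
    if (f < min(g) || f > max(g))
      stop(sprintf("ERI frequency %g Hz outside grid span", f))
    i <- findInterval(f, g, rightmost.closed = TRUE)
    if (g[i] == f) {
      mag <- stack$magnitude[, i]; ph <- stack$phase_rad[, i]
    } else {
      t <- (log(f) - log(g[i])) / (log(g[i + 1]) - log(g[i]))
      mag <- exp((1 - t) * log(stack$magnitude[, i]) + t * log(stack$magnitude[, i + 1]))
      ph <- (1 - t) * stack$phase_rad[, i] + t * stack$phase_rad[, i + 1]
    }
    Im(1 / (mag * exp(1i * ph)))
  }
  out <- eri(sig2(f_lf), sig2(f_hf), f_lf, f_hf)
  names(out) <- stack$grid$cell_id
  out
}

#' Schwarz-relation length scale of a relaxation time
#'
#' The electrochemical polarization of ions around a structure of radius r
#' relaxes on the time scale `tau = r^2 / (2 D)`; solving for the radius
#' and doubling gives the diameter `d = 2 sqrt(2 D tau)` of the polarizing
#' structure (e.g. a root storage-parenchyma cell).
#'
#' @param tau relaxation time in s, >= 0.
#' @param D ion diffusion coefficient in m^2/s (default 1e-9, a typical
#'   value; no temperature correction).
#' @return diameter in m. Strictly increasing in tau; inverts as
#'   `tau = d^2 / (8 D)`.
#' @export
schwarz_diameter <- function(tau, D = 1e-9) {
  if (any(tau < 0)) stop("tau must be >= 0")
  if (D <= 0) stop("D must be > 0")
  2 * sqrt(2 * D * tau)
}

#' @rdname schwarz_diameter
#' @return `schwarz_diameter_um`: the diameter in integer micrometres,
#'   truncated (the reporting convention for printed cell diameters).
#' @export
schwarz_diameter_um <- function(tau, D = 1e-9) {
  trunc(schwarz_diameter(tau, D) * 1e6)
}

#' Root biomass density of a plant
#'
#' Fresh root mass divided by the root-zone volume, in kg/m^3.
#'
#' @param fresh_root_mass_kg mass in kg.
#' @param zone a `root_zone` (or a volume in m^3).
#' @return RBD in kg/m^3.
#' @export
rbd <- function(fresh_root_mass_kg, zone) {
  v <- if (inherits(zone, "root_zone")) zone$v_rz else as.numeric(zone)
  if (any(v <= 0)) stop("zone volume must be > 0")
  fresh_root_mass_kg / v
}

#' Pearson correlation with significance
#'
#' Sample Pearson correlation coefficient and the two-sided p-value from
#' the t-distribution with n - 2 degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors, length >= 3, finite, nonzero variance.
#' @return list with `pc` and `p_value`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(pc = unname(ct$estimate), p_value = ct$p.value)
}
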