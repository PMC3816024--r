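#' Photon interaction data for a medium
#'
#' A material bundles a mass density with energy-indexed photon interaction
#' coefficients: the total mass attenuation coefficient \eqn{\mu/\rho}, the
#' mass energy-absorption coefficient \eqn{\mu_{en}/\rho}, and the fraction of
#' interactions that terminate the photon (photoelectric absorption; the
#' complement is incoherent Compton scattering). Coefficients are tabulated on
#' a strictly increasing energy grid and interpolated log-log between grid
#' points; queries outside the grid are errors, never extrapolations.
#'
#' @param name label for the medium.
#' @param density mass density in g cm^-3 (> 0).
#' @param energy_grid strictly increasing photon energies, MeV.
#' @param mu_over_rho total mass attenuation coefficient at each grid energy,
#'   cm^2 g^-1.
#' @param muen_over_rho mass energy-absorption coefficient at each grid
#'   energy, cm^2 g^-1; must not exceed `mu_over_rho` anywhere.
#' @param photoelectric_fraction fraction of interactions that are
#'   photoelectric absorption at each grid energy, in [0, 1].
#' @return An object of class `irk_material`.
#' @examples
#' m <- fictitious_material(0.1, photo_fraction = 1, density = 1)
#' attenuation_coefficient(m, 0.4)
#' @export
material <- function(name, density, energy_grid, mu_over_rho, muen_over_rho,
                     photoelectric_fraction) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    abort("`density` must be a single positive number (g cm^-3)")
  }
  ne <- length(energy_grid)
  if (ne < 2 || any(diff(energy_grid) <= 0) || any(energy_grid <= 0)) {
    abort("`energy_grid` must be strictly increasing and positive")
  }
  if (length(mu_over_rho) != ne || length(muen_over_rho) != ne ||
      length(photoelectric_fraction) != ne) {
    abort("coefficient columns must match the energy grid length")
  }
  if (any(mu_over_rho < 0) || any(muen_over_rho < 0)) {
    abort("interaction coefficients must be non-negative")
  }
  if (any(muen_over_rho > mu_over_rho * (1 + 1e-12))) {
    abort("muen_over_rho must not exceed mu_over_rho at any grid energy")
  }
  if (any(photoelectric_fraction < 0 | photoelectric_fraction > 1)) {
    abort("photoelectric_fraction must lie in [0, 1]")
  }
  structure(
    list(
      name = name, density = density,
      energy_grid = as.numeric(energy_grid),
      mu_over_rho = as.numeric(mu_over_rho),
      muen_over_rho = as.numeric(muen_over_rho),
      photoelectric_fraction = as.numeric(photoelectric_fraction),
      log_e = log(energy_grid),
      log_mu = log(pmax(mu_over_rho, 1e-300)),
      log_muen = log(pmax(muen_over_rho, 1e-300))
    ),
    class = "irk_material"
  )
}

#' @export
print.irk_material <- function(x, ...) {
  cat(sprintf("<irk_material> %s (density %.5g g cm^-3, %d grid points, %g-%g MeV)\n",
              x$name, x$density, length(x$energy_grid),
              min(x$energy_grid), max(x$energy_grid)))
  invisible(x)
}

check_energy_range <- function(material, energy) {
  lo <- material$energy_grid[1]
  hi <- material$energy_grid[length(material$energy_grid)]
  bad <- !is.finite(energy) | energy < lo | energy > hi
  if (any(bad)) {
    abort(sprintf(
      "energy %.6g MeV is outside the %s table range [%g, %g] MeV",
      energy[which(bad)[1]], material$name, lo, hi))
  }
  invisible(TRUE)
}

#' Interpolated interaction coefficients
#'
#' Log-log interpolation of the tabulated coefficients; exact at grid points.
#' `attenuation_coefficient()` returns the total mass attenuation coefficient
#' \eqn{\mu/\rho}, `energy_absorption_coefficient()` the mass energy-absorption
#' coefficient \eqn{\mu_{en}/\rho} (both cm^2 g^-1), and
#' `photoelectric_fraction_at()` the photoelectric branching fraction
#' (interpolated linearly against log energy). All are vectorised over
#' `energy` and raise an error naming the table bounds for any energy outside
#' the grid.
#'
#' @param material an [material()] object.
#' @param energy photon energies, MeV.
#' @return Numeric vector the length of `energy`.
#' @export
attenuation_coefficient <- function(material, energy) {
  check_energy_range(material, energy)
  zap_tiny(exp(approx(material$log_e, material$log_mu, xout = log(energy))$y))
}

# values below ~1e-290 only arise from the log-guard on exact zeros
zap_tiny <- function(x) {
  x[x < 1e-290] <- 0
  x
}

#' @rdname attenuation_coefficient
#' @export
energy_absorption_coefficient <- function(material, energy) {
  check_energy_range(material, energy)
  zap_tiny(exp(approx(material$log_e, material$log_muen, xout = log(energy))$y))
}

#' @rdname attenuation_coefficient
#' @export
photoelectric_fraction_at <- function(material, energy) {
  check_energy_range(material, energy)
  approx(material$log_e, material$photoelectric_fraction,
         xout = log(energy))$y
}

# fast unchecked interpolators used by the transport inner loops
mu_linear <- function(material, energy) {
  # linear attenuation coefficient, cm^-1
  zap_tiny(exp(approx(material$log_e, material$log_mu, xout = log(energy))$y)) *
    material$density
}
muen_mass <- function(material, energy) {
  zap_tiny(exp(approx(material$log_e, material$log_muen, xout = log(energy))$y))
}

#' Packaged materials
#'
#' `list_materials()` names the coefficient tables shipped with the package
#' (graphite, air, pmma, steel316, iridium); `load_material()` loads one, with
#' an optional density override (e.g. chamber-specific graphite densities).
#' `register_material_csv()` loads a user CSV with columns
#' `energy, mu_over_rho, muen_over_rho, photoelectric_fraction`.
#'
#' The packaged `mu/rho` and `muen/rho` columns are transcribed from the
#' standard published mass attenuation / mass energy-absorption compilations
#' on the conventional 0.01-1.5 MeV grid. Stainless steel uses the elemental
#' iron table (the alloy neighbours bracket iron); the iridium table is an
#' interpolation in atomic number between the tungsten and gold tables and is
#' used only for source-core self-absorption.
#'
#' @param name material name, one of `list_materials()`.
#' @param density optional density override, g cm^-3.
#' @return An `irk_material`.
#' @export
load_material <- function(name, density = NULL) {
  dir <- system.file("extdata", "materials", package = "irkwall")
  idx <- read.csv(file.path(dir, "index.csv"))
  if (!name %in% idx$name) {
    abort(sprintf("unknown material '%s'; see list_materials()", name))
  }
  path <- file.path(dir, paste0(name, ".csv"))
  register_material_csv(path, name = name,
                        density = density %||% idx$density[idx$name == name])
}

#' @rdname load_material
#' @export
list_materials <- function() {
  dir <- system.file("extdata", "materials", package = "irkwall")
  read.csv(file.path(dir, "index.csv"))$name
}

#' @rdname load_material
#' @param path CSV file with the documented columns.
#' @export
register_material_csv <- function(path, name = basename(path), density) {
  df <- read.csv(path)
  need <- c("energy", "mu_over_rho", "muen_over_rho", "photoelectric_fraction")
  if (!all(need %in% names(df))) {
    abort(sprintf("material CSV must have columns %s",
                  paste(need, collapse = ", ")))
  }
  material(sub("\\.csv$", "", name), density, df$energy, df$mu_over_rho,
           df$muen_over_rho, df$photoelectric_fraction)
}

#' Fictitious test material with energy-independent coefficients
#'
#' Fixture generator for closed-form transport checks: a medium with constant
#' total mass attenuation `mu_const` at every grid energy and a constant
#' photoelectric branching fraction. By convention its energy-absorption
#' coefficient is `photo_fraction * mu_const`, so a pure absorber
#' (`photo_fraction = 1`) deposits the full collision kerma and a pure
#' scatterer (`photo_fraction = 0`) never terminates a photon by absorption.
#'
#' @param mu_const mass attenuation coefficient, cm^2 g^-1 (>= 0).
#' @param photo_fraction photoelectric branching fraction in [0, 1].
#' @param density mass density, g cm^-3 (> 0).
#' @param energy_grid grid on which the constants are tabulated.
#' @return An `irk_material`.
#' @export
fictitious_material <- function(mu_const, photo_fraction = 0, density = 1,
                                energy_grid = c(0.001, 0.01, 0.1, 1, 10)) {
  if (!is.numeric(mu_const) || mu_const < 0) {
    abort("`mu_const` must be >= 0")
  }
  if (photo_fraction < 0 || photo_fraction > 1) {
    abort("`photo_fraction` must lie in [0, 1]")
  }
  n <- length(energy_grid)
  material(sprintf("fictitious(mu=%g,pf=%g)", mu_const, photo_fraction),
           density, energy_grid,
           rep(mu_const, n), rep(photo_fraction * mu_const, n),
           rep(photo_fraction, n))
}
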