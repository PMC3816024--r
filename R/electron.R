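#' Electron CSDA range and stopping-power lookup
#'
#' Packaged electron collision stopping powers (MeV cm^2 g^-1) and CSDA
#' ranges (g cm^-2) for graphite and air, interpolated log-log; the basis of
#' the straight-ahead-CSDA cavity response estimator. `csda_range()` maps
#' energy to range, `csda_energy()` is its exact piecewise inverse (both are
#' piecewise power laws through the same knots).
#'
#' @param material_name `"graphite"` or `"air"`.
#' @return `electron_table()` returns a list with the raw columns and the
#'   log-grids used by the interpolators.
#' @export
electron_table <- function(material_name = c("graphite", "air")) {
  material_name <- match.arg(material_name)
  df <- electron_data()
  df <- df[df$material == material_name, ]
  list(material = material_name, energy = df$energy,
       stopping_power = df$stopping_power, csda_range = df$csda_range,
       log_e = log(df$energy), log_r = log(df$csda_range),
       log_s = log(df$stopping_power))
}

electron_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- read.csv(system.file("extdata", "electron_ranges.csv",
                                     package = "irkwall"))
    }
    cache
  }
})

#' @rdname electron_table
#' @param table an [electron_table()].
#' @param energy electron kinetic energies, MeV (clamped to the grid).
#' @export
csda_range <- function(table, energy) {
  e <- pmin(pmax(energy, table$energy[1]), tail(table$energy, 1))
  r <- exp(approx(table$log_e, table$log_r, xout = log(e))$y)
  # below the grid floor the range falls off faster than any tabulated
  # power; scale linearly to zero
  low <- energy < table$energy[1]
  r[low] <- r[low] * energy[low] / table$energy[1]
  r
}

#' @rdname electron_table
#' @param range residual CSDA ranges, g cm^-2.
#' @export
csda_energy <- function(table, range) {
  r0 <- table$csda_range[1]
  r <- pmin(pmax(range, r0), tail(table$csda_range, 1))
  e <- exp(approx(table$log_r, table$log_e, xout = log(r))$y)
  low <- range < r0
  e[low] <- table$energy[1] * pmax(range[low], 0) / r0
  e
}

# Compton recoil-electron direction cosine relative to the incident photon,
# from momentum conservation (photon momenta = energies in MeV units).
recoil_cosine <- function(energy, scattered_energy, cos_theta) {
  q <- sqrt(pmax(energy^2 + scattered_energy^2 -
                   2 * energy * scattered_energy * cos_theta, 1e-30))
  pmin(1, pmax(-1, (energy - scattered_energy * cos_theta) / q))
}

# Straight-ahead CSDA response: energy deposited in the chamber gas by
# secondary electrons born at `pos` with direction `u` and kinetic energy
# `e_kin` (weights `w`). The electron travels in a straight line, slowing
# per the CSDA range tables of the wall (graphite) and the cavity gas; the
# deposit is the energy it loses between entering and leaving the cavity
# sphere. Vectorised; returns a numeric vector of deposits (MeV).
csda_gas_deposit <- function(pos, u, e_kin, w, chamber, tab_wall, tab_gas) {
  ti <- sphere_ts(pos, u, chamber$inner_radius)
  hit <- !is.na(ti[, 1]) & ti[, 2] > 0
  dep <- numeric(length(e_kin))
  if (!any(hit)) return(dep)
  hh <- which(hit)
  t1 <- pmax(ti[hh, 1], 0)
  t2 <- ti[hh, 2]
  rho_w <- chamber$wall_material$density
  rho_g <- chamber$cavity_material$density
  r0 <- csda_range(tab_wall, e_kin[hh])
  r_entry <- r0 - rho_w * t1
  ok <- r_entry > 0
  if (!any(ok)) return(dep)
  oo <- hh[ok]
  # convert residual graphite range to an entry energy, then slow the
  # electron across the gas chord with the gas range scale
  e_entry <- csda_energy(tab_wall, r_entry[ok])
  rg <- csda_range(tab_gas, e_entry)
  rg_exit <- pmax(0, rg - rho_g * (t2[ok] - t1[ok]))
  e_exit <- csda_energy(tab_gas, rg_exit)
  dep[oo] <- w[oo] * pmax(0, e_entry - e_exit)
  dep
}
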