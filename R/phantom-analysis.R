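#' Dose ratios between source positions
#'
#' Elementwise dose ratios at every monitoring distance for the three source
#' locations (cavity surface points A and B versus the cavity central axis),
#' with relative standard errors propagated in quadrature. The A/B column is
#' the quotient of the other two by construction.
#'
#' @param central,at_A,at_B `irk_dose_profile` tibbles on identical distance
#'   grids ([simulate_phantom()]); central doses must be positive.
#' @return A tibble of class `irk_ratio_table` with columns `distance`,
#'   `ratio_A_over_central`, `ratio_B_over_central`, `ratio_A_over_B` and the
#'   propagated `rel_se_*` columns.
#' @export
dose_ratio_table <- function(central, at_A, at_B) {
  for (p in list(central, at_A, at_B)) {
    if (!inherits(p, "irk_dose_profile")) {
      abort("inputs must be irk_dose_profile objects")
    }
  }
  if (!isTRUE(all.equal(central$distance, at_A$distance)) ||
      !isTRUE(all.equal(central$distance, at_B$distance))) {
    abort("dose profiles are on different distance grids")
  }
  if (any(central$dose <= 0)) {
    abort("central-axis doses must be positive to form ratios")
  }
  ra <- at_A$dose / central$dose
  rb <- at_B$dose / central$dose
  out <- tibble(
    distance = central$distance,
    ratio_A_over_central = ra,
    ratio_B_over_central = rb,
    ratio_A_over_B = ra / rb,
    rel_se_A_over_central = sqrt(at_A$rel_se^2 + central$rel_se^2),
    rel_se_B_over_central = sqrt(at_B$rel_se^2 + central$rel_se^2),
    rel_se_A_over_B = sqrt(at_A$rel_se^2 + at_B$rel_se^2))
  class(out) <- c("irk_ratio_table", class(out))
  out
}

#' Surface-to-centre dose ratio of a profile
#'
#' Ratio of the dose at the outermost monitoring cube (phantom surface,
#' 9.75 cm by default) to the dose at the innermost cube (1.25 cm, the
#' nearest monitoring point to the phantom centre; no cube exists inside the
#' cavity itself).
#'
#' @param profile an `irk_dose_profile`.
#' @param surface,center distances of the two cubes, cm (must be on the
#'   profile grid).
#' @return Dimensionless ratio.
#' @export
surface_to_center_ratio <- function(profile, surface = 9.75, center = 1.25) {
  stopifnot(inherits(profile, "irk_dose_profile"))
  is <- which(abs(profile$distance - surface) < 1e-9)
  ic <- which(abs(profile$distance - center) < 1e-9)
  if (length(is) != 1 || length(ic) != 1) {
    abort(sprintf("profile must cover the %g cm and %g cm points",
                  center, surface))
  }
  profile$dose[is] / profile$dose[ic]
}

#' Minimum wall thickness for charged-particle equilibrium
#'
#' Converts the CSDA (continuous-slowing-down-approximation) range of the
#' most energetic Compton recoil electrons - 0.31 g cm^-2 in graphite for the
#' 687 keV electrons set in motion by the 885 keV Ir-192 line - into a
#' physical wall thickness at the nominal graphite density. The chamber wall
#' must be at least this thick for the cavity dose to equal collision kerma.
#'
#' @param csda_range_g_cm2 CSDA range, g cm^-2.
#' @param density graphite density, g cm^-3 (nominal 1.7).
#' @return Thickness in cm.
#' @export
cpe_wall_thickness <- function(csda_range_g_cm2 = 0.31, density = 1.7) {
  stopifnot(csda_range_g_cm2 > 0, density > 0)
  csda_range_g_cm2 / density
}

#' Write a ratio table or dose profile as CSV
#'
#' @param x an `irk_ratio_table` or `irk_dose_profile`.
#' @param path output CSV path.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
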