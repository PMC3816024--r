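#' Principal Ir-192 photon lines
#'
#' The embedded principal photon emissions of Ir-192 between 60 keV and
#' 885 keV: the gamma lines of the Pt-192/Os-192 daughters plus the K X-ray
#' groups, with intensities in photons per decay from the standard decay data
#' sheets. The three very weak lines above 1 MeV are omitted; the most
#' energetic line kept is 885 keV.
#'
#' @return A tibble with columns `energy` (MeV) and `intensity`
#'   (photons/decay), ascending in energy.
#' @export
bare_lines <- function() {
  path <- system.file("extdata", "ir192_lines.csv", package = "irkwall")
  as_tibble(read.csv(path))
}

#' @rdname bare_lines
#' @export
ir192_lines <- bare_lines

#' Binned photon fluence spectrum
#'
#' @param bin_edges strictly increasing bin edges, MeV.
#' @param fluence non-negative relative fluence per bin (length
#'   `length(bin_edges) - 1`), at least one positive entry.
#' @return A tibble of class `irk_spectrum` with columns `bin_lo`, `bin_hi`,
#'   `fluence`.
#' @export
spectrum <- function(bin_edges, fluence) {
  if (any(diff(bin_edges) <= 0)) abort("bin_edges must be strictly increasing")
  if (length(fluence) != length(bin_edges) - 1) {
    abort("fluence must have one entry per bin")
  }
  if (any(fluence < 0) || !any(fluence > 0)) {
    abort("fluence must be non-negative with at least one positive bin")
  }
  out <- tibble(bin_lo = head(bin_edges, -1), bin_hi = tail(bin_edges, -1),
                fluence = as.numeric(fluence))
  class(out) <- c("irk_spectrum", class(out))
  out
}

#' Capsule-attenuated Ir-192 fluence spectrum at the reference point
#'
#' Computes the relative photon fluence spectrum reaching the reference
#' air-kerma rate measurement point, 100 cm from the source axis in the plane
#' that perpendicularly bisects it. For every embedded decay line and every
#' point of a deterministic quadrature grid over the cylindrical active core,
#' the emission is attenuated by \eqn{e^{-\sum_i \mu_i \ell_i}} along the ray
#' to the reference point, where the path crosses the residual iridium core
#' and the steel capsule wall. Contributions accumulate into energy bins and
#' the result is normalised to unit total fluence. The intervening air column
#' is excluded (the reference air-kerma rate is defined corrected for air
#' attenuation and scattering).
#'
#' @param capsule an [capsule_spec()].
#' @param bin_edges spectrum bin edges, MeV (default 5 keV bins over
#'   0.06-0.90 MeV).
#' @param n_axial,n_radial,n_azimuthal quadrature grid over the core volume.
#' @param reference_distance scoring distance from the source axis, cm.
#' @return An `irk_spectrum` tibble.
#' @export
attenuated_spectrum <- function(capsule = capsule_spec(),
                                bin_edges = seq(0.06, 0.90, by = 0.005),
                                n_axial = 32, n_radial = 16,
                                n_azimuthal = 16,
                                reference_distance = 100) {
  stopifnot(inherits(capsule, "irk_capsule"),
            n_axial >= 1, n_radial >= 1, n_azimuthal >= 1)
  lines <- bare_lines()
  # volume-uniform quadrature nodes over the core cylinder (axis along z,
  # centred at the origin)
  zi <- (seq_len(n_axial) - 0.5) / n_axial
  z <- (zi - 0.5) * capsule$core_length
  rj <- capsule$core_radius * sqrt((seq_len(n_radial) - 0.5) / n_radial)
  ph <- 2 * pi * (seq_len(n_azimuthal) - 0.5) / n_azimuthal
  g <- expand.grid(z = z, r = rj, phi = ph)
  o <- cbind(g$r * cos(g$phi), g$r * sin(g$phi), g$z)
  det_pt <- c(reference_distance, 0, 0)
  d <- cbind(det_pt[1] - o[, 1], det_pt[2] - o[, 2], det_pt[3] - o[, 3])
  d <- d / sqrt(rowSums(d^2))
  # path through residual core (iridium) and through capsule steel:
  # regions are the core cylinder and the capsule cylinder minus the core
  # cylinder (the core cylinder is extended with air end gaps inside the
  # capsule; rays to a lateral detector exit through the radial wall)
  paths <- capsule_path_lengths(o, d, capsule)
  l_core <- paths$core
  l_steel <- paths$steel
  rho_core <- capsule$core_material$density
  rho_cap <- capsule$capsule_material$density
  flu <- numeric(length(bin_edges) - 1)
  for (i in seq_len(nrow(lines))) {
    e <- lines$energy[i]
    mu_c <- attenuation_coefficient(capsule$core_material, e) * rho_core
    mu_s <- attenuation_coefficient(capsule$capsule_material, e) * rho_cap
    transmitted <- mean(exp(-mu_c * l_core - mu_s * l_steel))
    bin <- findInterval(e, bin_edges, rightmost.closed = TRUE)
    if (bin < 1 || bin > length(flu)) {
      abort(sprintf("line at %.4f MeV falls outside the bin range", e))
    }
    flu[bin] <- flu[bin] + lines$intensity[i] * transmitted
  }
  spectrum(bin_edges, flu / sum(flu))
}

# Forward path lengths through the residual iridium core and the steel
# capsule for rays leaving points `o` (relative to the source centre, axis
# along z) in directions `d`.
capsule_path_lengths <- function(o, d, capsule) {
  half_core <- capsule$core_length / 2
  half_cap <- capsule$capsule_outer_length / 2
  core_iv <- cylinder_interval(o, d, capsule$core_radius,
                               -half_core, half_core)
  cap_iv <- cylinder_interval(o, d, capsule$capsule_outer_radius,
                              -half_cap, half_cap)
  inner_iv <- cylinder_interval(o, d, capsule$capsule_inner_radius,
                                -half_cap, half_cap)
  len <- function(iv) pmax(0, pmin(iv[, 2], Inf) - pmax(iv[, 1], 0))
  list(core = len(core_iv),
       steel = pmax(0, len(cap_iv) - len(inner_iv)))
}

#' Direction-dependent capsule transmission
#'
#' Transmission factor `exp(-mu_Ir l_Ir - mu_steel l_steel)` for photons
#' leaving the active core at offsets `o` (relative to the source centre,
#' capsule axis along z) in directions `d`, at the given energies. This is
#' the on-the-fly anisotropy of the encapsulated source: near-axial paths
#' cross the full residual core and the steel end caps and are strongly
#' self-absorbed.
#'
#' @param o n x 3 matrix of emission points relative to the source centre, cm.
#' @param d n x 3 matrix of unit emission directions.
#' @param energy photon energies, MeV (length n or scalar).
#' @param capsule an [capsule_spec()].
#' @return Transmission factors in (0, 1].
#' @export
capsule_transmission <- function(o, d, energy, capsule) {
  paths <- capsule_path_lengths(o, d, capsule)
  mu_c <- mu_linear(capsule$core_material, energy)
  mu_s <- mu_linear(capsule$capsule_material, energy)
  exp(-mu_c * paths$core - mu_s * paths$steel)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spec an `irk_spectrum`.
#' @return Mean of the bin midpoints weighted by fluence, MeV.
#' @export
spectrum_mean_energy <- function(spec) {
  stopifnot(inherits(spec, "irk_spectrum"))
  tot <- sum(spec$fluence)
  if (tot <= 0) abort("spectrum has all-zero fluence")
  sum((spec$bin_lo + spec$bin_hi) / 2 * spec$fluence) / tot
}

#' Sample photon energies from a binned spectrum
#'
#' Inverse-transform sampling over bins (uniform within a bin); reproducible
#' under a fixed RNG state.
#'
#' @param spec an `irk_spectrum`.
#' @param n number of samples.
#' @return Numeric vector of energies, MeV.
#' @export
sample_energy <- function(spec, n) {
  stopifnot(inherits(spec, "irk_spectrum"), n >= 1)
  idx <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$fluence)
  runif(n, spec$bin_lo[idx], spec$bin_hi[idx])
}

#' Read/write a spectrum as CSV
#'
#' Columns `bin_lo`, `bin_hi`, `fluence` (MeV, relative fluence per bin).
#'
#' @param spec an `irk_spectrum`.
#' @param path CSV file path.
#' @export
write_spectrum_csv <- function(spec, path) {
  write.csv(as.data.frame(spec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  spectrum(c(df$bin_lo, df$bin_hi[nrow(df)]), df$fluence)
}
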