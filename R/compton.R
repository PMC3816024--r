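#' Klein-Nishina differential cross section
#'
#' Unnormalised free-electron Klein-Nishina differential cross section in the
#' scattering-angle cosine, \eqn{d\sigma/d\cos\theta \propto r^2 (r + 1/r -
#' \sin^2\theta)} with \eqn{r = E'/E = 1/(1 + k(1 - \cos\theta))} and
#' \eqn{k = E/m_e c^2}. Used both by the sampler and by the quadrature
#' oracles in the test-suite.
#'
#' @param energy incident photon energy, MeV (scalar).
#' @param cos_theta scattering-angle cosine(s).
#' @return Unnormalised density values.
#' @export
kn_density <- function(energy, cos_theta) {
  k <- energy / .electron_rest_mev
  r <- 1 / (1 + k * (1 - cos_theta))
  r^2 * (r + 1 / r - (1 - cos_theta^2))
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Draws scattering-angle cosines from the free-electron Klein-Nishina
#' differential cross section (rejection sampling against a uniform envelope;
#' the density is bounded by its forward-scatter value) and applies the
#' Compton kinematic relation \eqn{E' = E / (1 + (E / m_e c^2)(1 -
#' \cos\theta))}. Passing `cos_polar` skips the sampling and evaluates the
#' kinematics deterministically (e.g. backscatter `cos_polar = -1`). The
#' azimuth is uniform and left to the caller (transport rotates directions
#' with a uniform azimuth).
#'
#' @param energy incident photon energies, MeV (> 0); vectorised.
#' @param cos_polar optional forced scattering cosines (recycled).
#' @return A tibble with columns `scattered_energy` (MeV), `cos_polar`, and
#'   `recoil_energy` (the Compton electron energy, MeV).
#' @examples
#' compton_scatter(0.885, cos_polar = -1)  # 687 keV recoil electron
#' @export
compton_scatter <- function(energy, cos_polar = NULL) {
  stopifnot(all(energy > 0))
  if (is.null(cos_polar)) {
    cos_polar <- kn_sample_cos(energy)
  } else {
    stopifnot(all(abs(cos_polar) <= 1))
    cos_polar <- rep_len(cos_polar, length(energy))
  }
  scattered <- energy / (1 + (energy / .electron_rest_mev) * (1 - cos_polar))
  tibble(scattered_energy = scattered, cos_polar = cos_polar,
         recoil_energy = energy - scattered)
}

# vectorised rejection sampler for the KN scattering cosine
kn_sample_cos <- function(energy) {
  n <- length(energy)
  out <- numeric(n)
  todo <- seq_len(n)
  # envelope: density is maximal at cos_theta = 1 where it equals 2
  guard <- 0
  while (length(todo) > 0 && (guard <- guard + 1) < 1000) {
    mu <- runif(length(todo), -1, 1)
    f <- kn_density(energy[todo], mu)
    acc <- runif(length(todo)) * 2 <= f
    out[todo[acc]] <- mu[acc]
    todo <- todo[!acc]
  }
  out
}

#' Sample the interaction type in a medium
#'
#' Branches each collision into photoelectric absorption (probability given by
#' the material's photoelectric fraction at that energy) or incoherent Compton
#' scattering. Coherent scattering is not modelled.
#'
#' @param material an [material()] object.
#' @param energy photon energies, MeV (vectorised).
#' @return Character vector `"photoelectric"` or `"incoherent"`.
#' @export
sample_interaction <- function(material, energy) {
  pf <- photoelectric_fraction_at(material, energy)
  ifelse(runif(length(energy)) < pf, "photoelectric", "incoherent")
}
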