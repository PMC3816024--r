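#' Monte Carlo run configuration
#'
#' @param n_histories number of primary photon histories (>= 1).
#' @param seed integer seed for the run's private RNG stream; `NULL` uses
#'   (and advances) the global stream.
#' @param photon_cutoff tracking cutoff energy, MeV. The effective cutoff is
#'   the larger of this and the floor of the material tables; a photon
#'   falling below it terminates (with a local deposit in the analog
#'   estimator).
#' @param estimator cavity response model. `"csda_response"` (the default
#'   for chamber runs) scores the energy that straight-ahead CSDA secondary
#'   electrons, born at sampled photon collisions in the wall and in the gas,
#'   lose while crossing the gas cavity - the dominant, wall-generated part
#'   of a Bragg-Gray cavity signal. `"track_length"` is the collision-kerma
#'   track-length estimator over gas chords and `"analog"` scores energy
#'   transferred at sampled gas collisions; both ignore wall-born electrons.
#' @param cone_half_angle_margin relative widening of the source cone beyond
#'   the half-angle subtending the chamber (importance sampling of the
#'   emission direction; the margin admits near-miss photons that can
#'   scatter into the chamber from the ambient air).
#' @param beam `"cone"` for the solid-angle source cone, `"pencil"` for a
#'   zero-impact-parameter pencil beam through the chamber centre (used by
#'   closed-form attenuation checks).
#' @param batch_size histories per vectorised batch.
#' @return A list of class `irk_config`.
#' @export
run_config <- function(n_histories = 1e6, seed = NULL, photon_cutoff = 0.001,
                       estimator = c("csda_response", "track_length", "analog"),
                       cone_half_angle_margin = 0.1, beam = c("cone", "pencil"),
                       batch_size = 5e5) {
  stopifnot(n_histories >= 1, photon_cutoff > 0, cone_half_angle_margin >= 0)
  structure(list(n_histories = as.numeric(n_histories), seed = seed,
                 photon_cutoff = photon_cutoff,
                 estimator = match.arg(estimator),
                 cone_half_angle_margin = cone_half_angle_margin,
                 beam = match.arg(beam),
                 batch_size = as.numeric(batch_size)),
            class = "irk_config")
}

# shared deposit formula for the track-length collision-kerma estimator
cavity_deposit <- function(energy, weight, chord, cavity_material) {
  weight * energy * muen_mass(cavity_material, energy) *
    cavity_material$density * chord
}

#' Tally accumulator for tagged cavity energy deposits
#'
#' Running sums of primary (`sum_primary`), attenuation-unfolded primary
#' (`sum_primary_unatt`, each primary deposit carrying `exp(+wall optical
#' depth)`), and scattered (`sum_scatter`) cavity energy deposits, with
#' history-by-history second moments for uncertainty estimation.
#' `score_cavity_track()` adds one track-length deposit for the current
#' history; `finalize_history()` closes the history and folds its deposits
#' into the moment sums. The transport engine accumulates deposits with the
#' same formula, vectorised.
#'
#' @param cavity_material the cavity [material()] (air for real chambers).
#' @return A list of class `irk_tally`.
#' @export
new_tally <- function(cavity_material) {
  structure(
    list(sums = c(primary = 0, primary_unatt = 0, scatter = 0),
         sumsq = c(primary = 0, primary_unatt = 0, scatter = 0, total = 0),
         pending = c(primary = 0, primary_unatt = 0, scatter = 0),
         n_histories = 0, cavity_material = cavity_material,
         estimator = "track_length"),
    class = "irk_tally")
}

#' @rdname new_tally
#' @param tally an `irk_tally`.
#' @param state photon state: a list with `energy` (MeV), `weight`,
#'   `n_scatters`, and `wall_optical_depth` (dimensionless, accumulated in
#'   wall material while unscattered).
#' @param chord cavity path length for this deposit, cm (>= 0).
#' @export
score_cavity_track <- function(tally, state, chord) {
  stopifnot(inherits(tally, "irk_tally"))
  if (chord < 0) abort("chord must be >= 0")
  if (chord == 0) return(tally)
  dep <- cavity_deposit(state$energy, state$weight, chord,
                        tally$cavity_material)
  if (state$n_scatters == 0) {
    tally$pending["primary"] <- tally$pending["primary"] + dep
    tally$pending["primary_unatt"] <- tally$pending["primary_unatt"] +
      dep * exp(state$wall_optical_depth)
  } else {
    tally$pending["scatter"] <- tally$pending["scatter"] + dep
  }
  tally
}

#' @rdname new_tally
#' @export
finalize_history <- function(tally) {
  p <- tally$pending
  tally$sums <- tally$sums + p
  tally$sumsq <- tally$sumsq +
    c(p^2, total = unname((p["primary"] + p["scatter"])^2))
  tally$pending[] <- 0
  tally$n_histories <- tally$n_histories + 1
  tally
}

effective_cutoff <- function(config, materials) {
  floors <- vapply(materials, function(m) m$energy_grid[1], numeric(1))
  max(config$photon_cutoff, max(floors))
}

#' Simulate a chamber irradiation
#'
#' Transports photons from a point source at `(0, 0, -source_distance)`
#' through ambient air, graphite wall, and air cavity, scoring tagged cavity
#' energy deposits with the configured response estimator (by default the
#' straight-ahead-CSDA secondary-electron response; see [run_config()]).
#' Emission directions are importance-sampled in the
#' cone subtending the chamber (plus a configurable margin), each history
#' representing `cone_fraction` of an isotropic emission. Primary (never
#' scattered) deposits also accumulate with the attenuation-unfolding weight
#' `exp(+mu t)`, `t` being the wall path the photon crossed before entering
#' the cavity, which yields the wall correction factors via [wall_factors()].
#'
#' Interactions are photoelectric absorption or incoherent (Klein-Nishina)
#' Compton scattering; coherent scattering and fluorescence are not modelled.
#'
#' @param chamber an [chamber_spec()].
#' @param source an `irk_spectrum` or a single monoenergetic energy in MeV.
#' @param config an [run_config()].
#' @return An `irk_tally` with per-history moment sums, the cone fraction,
#'   and run metadata.
#' @export
simulate_chamber <- function(chamber, source, config = run_config()) {
  stopifnot(inherits(chamber, "irk_chamber"), inherits(config, "irk_config"))
  mono <- is.numeric(source) && length(source) == 1
  if (!mono && !inherits(source, "irk_spectrum")) {
    abort("source must be an irk_spectrum or a single energy (MeV)")
  }
  mats <- list(chamber$ambient_material, chamber$wall_material,
               chamber$cavity_material)
  cutoff <- effective_cutoff(config, mats)
  emax <- min(vapply(mats, function(m) max(m$energy_grid), numeric(1)))
  if (mono && (source < cutoff || source > emax)) {
    abort(sprintf("source energy must lie within [%g, %g] MeV", cutoff, emax))
  }
  D <- chamber$source_distance
  sin_sub <- chamber$outer_radius / D
  theta <- asin(sin_sub) * (1 + config$cone_half_angle_margin)
  if (theta >= pi / 2) theta <- pi / 2 - 1e-9
  mu_min <- cos(theta)
  cone_fraction <- (1 - mu_min) / 2
  r_amb <- D + 10

  resp <- if (config$estimator == "csda_response") {
    pick <- function(m, fallback) {
      if (m$name %in% c("graphite", "air")) electron_table(m$name)
      else electron_table(fallback)
    }
    list(wall = pick(chamber$wall_material, "graphite"),
         gas = pick(chamber$cavity_material, "air"))
  } else NULL

  with_local_seed(config$seed, {
    tal <- new_tally(chamber$cavity_material)
    tal$estimator <- config$estimator
    n_left <- config$n_histories
    while (n_left > 0) {
      nb <- as.integer(min(n_left, config$batch_size))
      n_left <- n_left - nb
      E <- if (mono) rep(source, nb) else sample_energy(source, nb)
      pos <- cbind(0, 0, rep(-D, nb))
      dir <- if (config$beam == "pencil") {
        cbind(0, 0, rep(1, nb))
      } else {
        cone_directions(nb, mu_min)
      }
      st <- list(pos = pos, dir = dir, E = E, w = rep(1, nb),
                 nsc = rep(0L, nb), hid = seq_len(nb))
      d_p <- numeric(nb); d_u <- numeric(nb); d_s <- numeric(nb)
      flights <- 0
      while (length(st$E) > 0 && (flights <- flights + 1) < 500) {
        res <- chamber_flight(st, chamber, config, cutoff, resp)
        dp <- res$deposits
        if (length(dp$hid)) {
          pri <- dp$primary
          idx <- dp$hid[pri]
          d_p[idx] <- d_p[idx] + dp$dep[pri]
          d_u[idx] <- d_u[idx] + dp$dep[pri] * exp(dp$wtau[pri])
          idx <- dp$hid[!pri]
          d_s[idx] <- d_s[idx] + dp$dep[!pri]
        }
        st <- res$next_state
      }
      tal$sums <- tal$sums +
        c(primary = sum(d_p), primary_unatt = sum(d_u), scatter = sum(d_s))
      tal$sumsq <- tal$sumsq +
        c(primary = sum(d_p^2), primary_unatt = sum(d_u^2),
          scatter = sum(d_s^2), total = sum((d_p + d_s)^2))
      tal$n_histories <- tal$n_histories + nb
    }
    tal$cone_fraction <- cone_fraction
    tal$chamber <- chamber$name
    tal$source <- if (mono) sprintf("%g MeV", source) else "spectrum"
    tal$seed <- config$seed
    tal
  })
}

# One flight (free path + interaction) for all active chamber photons.
# Returns cavity deposits made during the flight and the surviving
# (scattered) photon states.
chamber_flight <- function(st, chamber, config, cutoff, resp = NULL) {
  n <- length(st$E)
  amb <- chamber$ambient_material
  wal <- chamber$wall_material
  cav <- chamber$cavity_material
  D <- chamber$source_distance
  m <- chamber_milestones(st$pos, st$dir, chamber$inner_radius,
                          chamber$outer_radius, D + 10)
  mu_a <- mu_linear(amb, st$E)
  mu_w <- mu_linear(wal, st$E)
  mu_c <- mu_linear(cav, st$E)
  L <- cbind(m[, 1], m[, 2] - m[, 1], m[, 3] - m[, 2],
             m[, 4] - m[, 3], m[, 5] - m[, 4])
  mu_seg <- cbind(mu_a, mu_w, mu_c, mu_w, mu_a)
  tau <- L * mu_seg
  Tc <- tau
  for (k in 2:5) Tc[, k] <- Tc[, k] + Tc[, k - 1]
  xi <- rexp(n)
  esc <- xi > Tc[, 5]
  j <- 1L + (xi > Tc[, 1]) + (xi > Tc[, 2]) + (xi > Tc[, 3]) + (xi > Tc[, 4])
  j[esc] <- 6L
  prev_T <- cbind(0, Tc)[cbind(seq_len(n), j)]
  prev_m <- cbind(0, m)[cbind(seq_len(n), j)]
  mu_at <- cbind(mu_seg, mu_a)[cbind(seq_len(n), pmin(j, 5L))]
  t_int <- ifelse(esc, m[, 5], prev_m + (xi - prev_T) / pmax(mu_at, 1e-300))

  # cavity path traversed during this flight
  ell <- pmax(0, pmin(t_int, m[, 3]) - m[, 2])
  # wall optical depth crossed before entering the cavity (primaries enter
  # the cavity on their first flight, so no carried depth is needed)
  wtau_entry <- mu_w * L[, 2]

  deposits <- list(hid = integer(0))
  if (config$estimator == "track_length") {
    hit <- ell > 0
    if (any(hit)) {
      deposits <- list(
        hid = st$hid[hit],
        dep = cavity_deposit(st$E[hit], st$w[hit], ell[hit], cav),
        primary = st$nsc[hit] == 0L,
        wtau = wtau_entry[hit])
    }
  }

  inter <- !esc
  next_state <- list(pos = matrix(numeric(0), 0, 3),
                     dir = matrix(numeric(0), 0, 3), E = numeric(0),
                     w = numeric(0), nsc = integer(0), hid = integer(0))
  if (!any(inter)) return(list(deposits = deposits, next_state = next_state))

  ii <- which(inter)
  Ei <- st$E[ii]
  # interaction region follows from the segment index
  reg <- c(1L, 2L, 3L, 2L, 1L)[j[ii]]
  pf <- numeric(length(ii))
  for (k in 1:3) {
    sel <- reg == k
    if (any(sel)) {
      pf[sel] <- photoelectric_fraction_at(list(amb, wal, cav)[[k]], Ei[sel])
    }
  }
  photo <- runif(length(ii)) < pf
  sc <- compton_scatter(Ei)
  e_new <- sc$scattered_energy
  dead_soft <- e_new < cutoff
  if (config$estimator == "analog") {
    in_cav <- j[ii] == 3L
    # energy transferred to electrons at the collision (plus the residual
    # energy of photons terminated below the cutoff, deposited locally)
    transfer <- ifelse(photo, Ei,
                       Ei - ifelse(dead_soft, 0, e_new))
    hit <- in_cav & transfer > 0
    if (any(hit)) {
      deposits <- list(
        hid = st$hid[ii][hit],
        dep = st$w[ii][hit] * transfer[hit],
        primary = st$nsc[ii][hit] == 0L,
        wtau = wtau_entry[ii][hit])
    }
  }
  if (config$estimator == "csda_response") {
    # secondary electrons from collisions in the wall or the gas; ambient
    # collisions cannot reach the cavity (the wall exceeds the CSDA range)
    inside <- reg >= 2L
    if (any(inside)) {
      ci <- ii[inside]
      e_kin <- ifelse(photo[inside], Ei[inside], sc$recoil_energy[inside])
      cos_e <- ifelse(photo[inside], 1,
                      recoil_cosine(Ei[inside], e_new[inside],
                                    sc$cos_polar[inside]))
      cpos <- st$pos[ci, , drop = FALSE] + t_int[ci] * st$dir[ci, , drop = FALSE]
      # average the gas deposit over the electron azimuth (randomly rotated
      # comb): same expectation as sampling one azimuth, far lower variance
      K <- 16L
      zeta <- runif(length(ci))
      dep <- 0
      for (kk in seq_len(K)) {
        phi_k <- 2 * pi * (kk - 1 + zeta) / K
        u <- rotate_directions(st$dir[ci, , drop = FALSE], cos_e, phi_k)
        dep <- dep + csda_gas_deposit(cpos, u, e_kin, st$w[ci], chamber,
                                      resp$wall, resp$gas)
      }
      dep <- dep / K
      # wall optical depth traversed by the photon up to the collision
      wtau_coll <- mu_w[ci] *
        (pmax(0, pmin(t_int[ci], m[ci, 2]) - m[ci, 1]) +
           pmax(0, t_int[ci] - m[ci, 3]))
      hit <- dep > 0
      if (any(hit)) {
        deposits <- list(
          hid = st$hid[ci][hit],
          dep = dep[hit],
          primary = st$nsc[ci][hit] == 0L,
          wtau = wtau_coll[hit])
      }
    }
  }
  keep <- !photo & !dead_soft
  if (any(keep)) {
    kk <- ii[keep]
    newpos <- st$pos[kk, , drop = FALSE] + t_int[kk] * st$dir[kk, , drop = FALSE]
    newdir <- rotate_directions(st$dir[kk, , drop = FALSE], sc$cos_polar[keep])
    next_state <- list(pos = newpos, dir = newdir, E = e_new[keep],
                       w = st$w[kk], nsc = st$nsc[kk] + 1L, hid = st$hid[kk])
  }
  list(deposits = deposits, next_state = next_state)
}

#' @export
print.irk_tally <- function(x, ...) {
  cat(sprintf(
    "<irk_tally> %s histories (%s estimator)%s\n  sums: primary %.6g, unfolded %.6g, scatter %.6g\n",
    format(x$n_histories, big.mark = ","), x$estimator,
    if (!is.null(x$chamber)) paste0(", chamber ", x$chamber) else "",
    x$sums["primary"], x$sums["primary_unatt"], x$sums["scatter"]))
  invisible(x)
}
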