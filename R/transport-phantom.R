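#' Simulate the phantom dose profile for a displaced source
#'
#' Transports photons emitted inside the cylindrical phantom's axial air
#' cavity and scores photon kerma (dose under the kerma approximation) in
#' 0.5 cm cubes centred along the monitoring line: the +x radius at the
#' source height. The source sits either on the cavity axis
#' (`"central_axis"`) or displaced to the cavity surface at the source
#' height: point B on the side nearest the monitoring line, point A
#' diametrically opposite. By default the encapsulated source is modelled
#' explicitly (see `source_model`).
#'
#' With `first_flight = "deterministic"` (default) the uncollided kerma is
#' computed by a deterministic Fibonacci-lattice quadrature over emission
#' directions (exact exponential attenuation along each ray, analytic
#' integral across each cube) and only the scattered field is simulated, by
#' forcing the first collision and then transporting analog Compton photons
#' with track-length scoring. `"analog"` scores everything by the
#' track-length Monte Carlo estimator; the two agree within statistics.
#'
#' @param phantom an [phantom_spec()].
#' @param source_position `"central_axis"`, `"A"` or `"B"`.
#' @param source only for `source_model = "point"`: an `irk_spectrum`
#'   (default: the capsule-attenuated Ir-192 spectrum) or a monoenergetic
#'   energy, MeV. The `"capsule"` model carries its own emission physics and
#'   requires `source = NULL`.
#' @param config an [run_config()].
#' @param cube_centers scoring-cube centre distances from the cavity axis, cm.
#' @param cube_half half side length of the scoring cubes, cm.
#' @param first_flight `"deterministic"` or `"analog"`.
#' @param n_uncollided_dirs directions in the uncollided quadrature.
#' @param source_model `"capsule"` (default) models the encapsulated source
#'   explicitly: emission points uniform over the finite active core cylinder
#'   (axis along z, centred at the source position), energies drawn from the
#'   bare decay lines, and every emission weighted by the direction-dependent
#'   transmission through the residual iridium core and the steel capsule.
#'   Near-axial emission is strongly self-absorbed (end-on core paths), which
#'   matters when a scoring cube touches the source. `"point"` is an
#'   isotropic point emitter at the exact position with the supplied
#'   `source` spectrum (used by the closed-form inverse-square checks).
#' @param core an [capsule_spec()] providing the core/capsule geometry.
#' @return A tibble of class `irk_dose_profile` with columns `distance` (cm),
#'   `dose` (Gy per emitted photon), `rel_se` (relative standard error of the
#'   Monte Carlo component), `uncollided`, `scattered`, `source_position`.
#' @export
simulate_phantom <- function(phantom, source_position = c("central_axis", "A", "B"),
                             source = NULL, config = run_config(),
                             cube_centers = seq(1.25, 9.75, by = 0.5),
                             cube_half = 0.25,
                             first_flight = c("deterministic", "analog"),
                             n_uncollided_dirs = 2e5,
                             source_model = c("capsule", "point"),
                             core = capsule_spec()) {
  stopifnot(inherits(phantom, "irk_phantom"), inherits(config, "irk_config"))
  source_position <- match.arg(source_position)
  first_flight <- match.arg(first_flight)
  source_model <- match.arg(source_model)
  mono <- FALSE
  if (source_model == "capsule") {
    if (!is.null(source)) {
      abort("the capsule source model carries its own emission spectrum; use source_model = \"point\" to supply one")
    }
    lines <- bare_lines()
  } else {
    if (is.null(source)) source <- attenuated_spectrum()
    mono <- is.numeric(source) && length(source) == 1
    if (!mono && !inherits(source, "irk_spectrum")) {
      abort("source must be an irk_spectrum or a single energy (MeV)")
    }
  }
  h <- phantom$source_height
  # A rigid capsule "at the cavity surface" rests tangent to it: its axis
  # sits one capsule radius inside. The point model uses the surface itself.
  r_src <- if (source_model == "capsule") {
    phantom$cavity_radius - core$capsule_outer_radius
  } else {
    phantom$cavity_radius
  }
  if (r_src <= 0) abort("capsule does not fit inside the cavity")
  src <- switch(source_position,
                central_axis = c(0, 0, h),
                A = c(-r_src, 0, h),
                B = c(r_src, 0, h))
  cubes <- lapply(cube_centers, function(x) {
    list(lo = c(x - cube_half, -cube_half, h - cube_half),
         hi = c(x + cube_half, cube_half, h + cube_half))
  })
  vol <- (2 * cube_half)^3
  mats <- list(phantom$body_material, phantom$cavity_material)
  cutoff <- effective_cutoff(config, mats)
  nc <- length(cubes)
  n <- config$n_histories

  # energy weights for the deterministic component
  if (source_model == "capsule") {
    e_det <- lines$energy
    w_det <- lines$intensity / sum(lines$intensity)
  } else if (mono) {
    e_det <- source; w_det <- 1
  } else {
    keep <- source$fluence > 0
    e_det <- (source$bin_lo[keep] + source$bin_hi[keep]) / 2
    w_det <- source$fluence[keep] / sum(source$fluence[keep])
  }

  unc <- if (first_flight == "deterministic") {
    uncollided_cube_dose(phantom, src, e_det, w_det, cubes, vol,
                         n_uncollided_dirs,
                         offsets = if (source_model == "capsule")
                           core_offset_lattice(core) else NULL,
                         capsule = if (source_model == "capsule") core)
  } else {
    rep(0, nc)
  }

  mc <- with_local_seed(config$seed, {
    sum_d <- numeric(nc); sum_d2 <- numeric(nc)
    n_left <- n
    while (n_left > 0) {
      nb <- as.integer(min(n_left, config$batch_size))
      n_left <- n_left - nb
      if (source_model == "capsule") {
        li <- sample.int(nrow(lines), nb, replace = TRUE,
                         prob = lines$intensity)
        E <- lines$energy[li]
        off <- core_offset_sample(nb, core)
        dir0 <- isotropic_directions(nb)
        w0 <- capsule_transmission(off, dir0, E, core)
        emit <- matrix(src, nb, 3, byrow = TRUE) + off
      } else {
        E <- if (mono) rep(source, nb) else sample_energy(source, nb)
        dir0 <- isotropic_directions(nb)
        w0 <- rep(1, nb)
        emit <- matrix(src, nb, 3, byrow = TRUE)
      }
      st <- list(pos = emit, dir = dir0,
                 E = E, w = w0, nsc = rep(0L, nb), hid = seq_len(nb))
      dmat <- matrix(0, nb, nc)
      if (first_flight == "deterministic") {
        st <- phantom_first_collision(st, phantom, cutoff)
      }
      flights <- 0
      while (length(st$E) > 0 && (flights <- flights + 1) < 1000) {
        res <- phantom_flight(st, phantom, cutoff, cubes,
                              score_all = (first_flight == "analog"))
        dp <- res$deposits
        if (length(dp$hid)) {
          dmat[cbind(dp$hid, dp$cube)] <- dmat[cbind(dp$hid, dp$cube)] + dp$dep
        }
        st <- res$next_state
      }
      sum_d <- sum_d + colSums(dmat)
      sum_d2 <- sum_d2 + colSums(dmat^2)
    }
    list(mean = sum_d / n,
         se = sqrt(pmax(0, sum_d2 / n - (sum_d / n)^2) / n))
  })

  # flight deposits are scored directly in Gy per history
  scattered <- mc$mean
  dose <- unc + scattered
  out <- tibble(distance = as.numeric(cube_centers), dose = dose,
                rel_se = ifelse(dose > 0, mc$se / dose, 0),
                uncollided = unc, scattered = scattered,
                source_position = source_position)
  class(out) <- c("irk_dose_profile", class(out))
  attr(out, "n_histories") <- n
  attr(out, "seed") <- config$seed
  attr(out, "first_flight") <- first_flight
  attr(out, "source_model") <- source_model
  out
}

# Uniform sample of emission points over the active core cylinder (axis
# along z, centred at the origin).
core_offset_sample <- function(n, core) {
  z <- runif(n, -core$core_length / 2, core$core_length / 2)
  r <- core$core_radius * sqrt(runif(n))
  ph <- runif(n, 0, 2 * pi)
  cbind(r * cos(ph), r * sin(ph), z)
}

# Deterministic lattice of emission points over the core cylinder, cycled
# across quadrature directions.
core_offset_lattice <- function(core, n_z = 16, n_r = 2, n_phi = 2) {
  z <- ((seq_len(n_z) - 0.5) / n_z - 0.5) * core$core_length
  r <- core$core_radius * sqrt((seq_len(n_r) - 0.5) / n_r)
  ph <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  g <- expand.grid(z = z, r = r, ph = ph)
  cbind(g$r * cos(g$ph), g$r * sin(g$ph), g$z)
}

# Deterministic uncollided cube-averaged kerma, Gy per emitted photon:
# (1/N) sum over lattice directions of the attenuated track-length integral
# across each cube, times E * muen/rho / V per energy. `offsets` (k x 3)
# distributes the emission point over a finite source, cycled across the
# direction lattice.
uncollided_cube_dose <- function(phantom, src, energies, weights, cubes, vol,
                                 n_dirs, offsets = NULL, capsule = NULL) {
  body <- phantom$body_material
  cav <- phantom$cavity_material
  d <- fibonacci_sphere(n_dirs)
  rel_o <- matrix(0, n_dirs, 3)
  if (!is.null(offsets)) {
    idx <- rep_len(seq_len(nrow(offsets)), n_dirs)
    rel_o <- offsets[idx, , drop = FALSE]
  }
  o <- matrix(src, n_dirs, 3, byrow = TRUE) + rel_o
  cap_paths <- if (!is.null(capsule)) capsule_path_lengths(rel_o, d, capsule)
  m <- phantom_milestones(o, d, phantom)
  out <- numeric(length(cubes))
  for (k in seq_along(cubes)) {
    iv <- box_interval(o, d, cubes[[k]]$lo, cubes[[k]]$hi)
    b1 <- pmax(iv[, 1], 0); b2 <- pmin(iv[, 2], m[, 3])
    hit <- which(b2 > b1)
    if (!length(hit)) next
    # cavity (air) and body path lengths before cube entry
    a_len <- pmax(0, pmin(b1[hit], m[hit, 2]) - m[hit, 1])
    p_len <- b1[hit] - a_len
    ell <- b2[hit] - b1[hit]
    acc <- 0
    for (i in seq_along(energies)) {
      e <- energies[i]
      mu_a <- mu_linear(cav, e); mu_b <- mu_linear(body, e)
      muen <- muen_mass(body, e) * body$density
      atten <- exp(-mu_a * a_len - mu_b * p_len)
      if (!is.null(capsule)) {
        mu_core <- mu_linear(capsule$core_material, e)
        mu_steel <- mu_linear(capsule$capsule_material, e)
        atten <- atten * exp(-mu_core * cap_paths$core[hit] -
                               mu_steel * cap_paths$steel[hit])
      }
      inner <- if (mu_b > 0) (1 - exp(-mu_b * ell)) / mu_b else ell
      acc <- acc + weights[i] * e * muen * sum(atten * inner)
    }
    out[k] <- acc / n_dirs / (body$density * vol) * .mev_to_gy_per_g
  }
  out
}

# Forced first collision: every history collides exactly once on its first
# flight, with weight 1 - exp(-tau_escape); the uncollided remainder is
# handled deterministically. Returns post-collision (scattered) states.
phantom_first_collision <- function(st, phantom, cutoff) {
  n <- length(st$E)
  body <- phantom$body_material
  cav <- phantom$cavity_material
  m <- phantom_milestones(st$pos, st$dir, phantom)
  mu_b <- mu_linear(body, st$E)
  mu_c <- mu_linear(cav, st$E)
  L <- cbind(m[, 1], m[, 2] - m[, 1], m[, 3] - m[, 2])
  mu_seg <- cbind(mu_b, mu_c, mu_b)
  tau <- L * mu_seg
  Tc <- tau
  Tc[, 2] <- Tc[, 2] + Tc[, 1]
  Tc[, 3] <- Tc[, 3] + Tc[, 2]
  p_int <- -expm1(-Tc[, 3])
  keep <- p_int > 1e-12
  if (!any(keep)) {
    return(list(pos = matrix(numeric(0), 0, 3), dir = matrix(numeric(0), 0, 3),
                E = numeric(0), w = numeric(0), nsc = integer(0),
                hid = integer(0)))
  }
  kk <- which(keep)
  xi <- -log1p(-runif(length(kk)) * p_int[kk])
  j <- 1L + (xi > Tc[kk, 1]) + (xi > Tc[kk, 2])
  prev_T <- cbind(0, Tc)[cbind(kk, j)]
  prev_m <- cbind(0, m)[cbind(kk, j)]
  mu_at <- mu_seg[cbind(kk, j)]
  t_int <- prev_m + (xi - prev_T) / pmax(mu_at, 1e-300)
  Ei <- st$E[kk]
  reg_mat <- list(body, cav, body)
  pf <- numeric(length(kk))
  for (r in 1:3) {
    sel <- j == r
    if (any(sel)) pf[sel] <- photoelectric_fraction_at(reg_mat[[r]], Ei[sel])
  }
  photo <- runif(length(kk)) < pf
  sc <- compton_scatter(Ei)
  surv <- !photo & sc$scattered_energy >= cutoff
  if (!any(surv)) {
    return(list(pos = matrix(numeric(0), 0, 3), dir = matrix(numeric(0), 0, 3),
                E = numeric(0), w = numeric(0), nsc = integer(0),
                hid = integer(0)))
  }
  ss <- which(surv)
  rows <- kk[ss]
  newpos <- st$pos[rows, , drop = FALSE] +
    t_int[ss] * st$dir[rows, , drop = FALSE]
  newdir <- rotate_directions(st$dir[rows, , drop = FALSE], sc$cos_polar[ss])
  list(pos = newpos, dir = newdir, E = sc$scattered_energy[ss],
       w = st$w[rows] * p_int[rows], nsc = rep(1L, length(ss)),
       hid = st$hid[rows])
}

# One analog flight for phantom photons with track-length cube scoring.
# score_all = FALSE scores only scattered (nsc >= 1) photons.
phantom_flight <- function(st, phantom, cutoff, cubes, score_all) {
  n <- length(st$E)
  body <- phantom$body_material
  cav <- phantom$cavity_material
  vol <- prod(cubes[[1]]$hi - cubes[[1]]$lo)
  m <- phantom_milestones(st$pos, st$dir, phantom)
  mu_b <- mu_linear(body, st$E)
  mu_c <- mu_linear(cav, st$E)
  L <- cbind(m[, 1], m[, 2] - m[, 1], m[, 3] - m[, 2])
  mu_seg <- cbind(mu_b, mu_c, mu_b)
  tau <- L * mu_seg
  Tc <- tau
  Tc[, 2] <- Tc[, 2] + Tc[, 1]
  Tc[, 3] <- Tc[, 3] + Tc[, 2]
  xi <- rexp(n)
  esc <- xi > Tc[, 3]
  j <- 1L + (xi > Tc[, 1]) + (xi > Tc[, 2])
  j[esc] <- 4L
  prev_T <- cbind(0, Tc)[cbind(seq_len(n), j)]
  prev_m <- cbind(0, m)[cbind(seq_len(n), j)]
  mu_at <- cbind(mu_seg, mu_b)[cbind(seq_len(n), pmin(j, 3L))]
  t_end <- ifelse(esc, m[, 3], prev_m + (xi - prev_T) / pmax(mu_at, 1e-300))

  # track-length scoring across the monitoring cubes
  hid_out <- integer(0); cube_out <- integer(0); dep_out <- numeric(0)
  score <- if (score_all) rep(TRUE, n) else st$nsc >= 1L
  if (any(score)) {
    muen_lin <- muen_mass(body, st$E) * body$density
    for (k in seq_along(cubes)) {
      iv <- box_interval(st$pos, st$dir, cubes[[k]]$lo, cubes[[k]]$hi)
      b1 <- pmax(iv[, 1], 0)
      b2 <- pmin(iv[, 2], t_end)
      hit <- which(score & b2 > b1)
      if (length(hit)) {
        ell <- b2[hit] - b1[hit]
        dep <- st$w[hit] * st$E[hit] * muen_lin[hit] * ell /
          (body$density * vol) * .mev_to_gy_per_g
        hid_out <- c(hid_out, st$hid[hit])
        cube_out <- c(cube_out, rep.int(k, length(hit)))
        dep_out <- c(dep_out, dep)
      }
    }
  }
  deposits <- list(hid = hid_out, cube = cube_out, dep = dep_out)

  inter <- !esc
  next_state <- list(pos = matrix(numeric(0), 0, 3),
                     dir = matrix(numeric(0), 0, 3), E = numeric(0),
                     w = numeric(0), nsc = integer(0), hid = integer(0))
  if (!any(inter)) return(list(deposits = deposits, next_state = next_state))
  ii <- which(inter)
  Ei <- st$E[ii]
  reg_mat <- list(body, cav, body)
  pf <- numeric(length(ii))
  for (r in 1:3) {
    sel <- j[ii] == r
    if (any(sel)) pf[sel] <- photoelectric_fraction_at(reg_mat[[r]], Ei[sel])
  }
  photo <- runif(length(ii)) < pf
  sc <- compton_scatter(Ei)
  keep <- !photo & sc$scattered_energy >= cutoff
  if (any(keep)) {
    kk <- ii[keep]
    newpos <- st$pos[kk, , drop = FALSE] + t_end[kk] * st$dir[kk, , drop = FALSE]
    newdir <- rotate_directions(st$dir[kk, , drop = FALSE], sc$cos_polar[keep])
    next_state <- list(pos = newpos, dir = newdir,
                       E = sc$scattered_energy[keep], w = st$w[kk],
                       nsc = st$nsc[kk] + 1L, hid = st$hid[kk])
  }
  list(deposits = deposits, next_state = next_state)
}
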