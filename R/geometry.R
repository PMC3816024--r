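#' Construct a ray
#'
#' A ray is an origin (cm) and a unit direction. The direction is validated
#' to unit length within 1e-12 after an optional normalisation.
#'
#' @param origin numeric length-3 point, cm.
#' @param direction numeric length-3 vector; normalised unless `normalize =
#'   FALSE`, in which case it must already be unit to 1e-12.
#' @param normalize normalise `direction` to unit length.
#' @return Object of class `irk_ray`.
#' @export
ray <- function(origin, direction, normalize = TRUE) {
  stopifnot(length(origin) == 3, length(direction) == 3,
            all(is.finite(origin)), all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("ray direction must be non-zero")
  if (normalize) {
    direction <- direction / nrm
  } else if (abs(nrm - 1) > 1e-12) {
    abort("ray direction must be unit length to 1e-12")
  }
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction)), class = "irk_ray")
}

# --- internal vectorised primitives -------------------------------------

# Crossing times with the sphere |x| = R for rows of origins o (n x 3) and
# unit directions d. Returns cbind(t1, t2); NA where the ray misses.
sphere_ts <- function(o, d, R) {
  b <- rowSums(o * d)
  cc <- rowSums(o * o) - R^2
  disc <- b * b - cc
  s <- sqrt(pmax(disc, 0))
  t1 <- -b - s
  t2 <- -b + s
  miss <- disc <= 0
  t1[miss] <- NA_real_
  t2[miss] <- NA_real_
  cbind(t1, t2)
}

# Parameter interval of a ray inside the capped cylinder x^2 + y^2 <= R^2,
# z0 <= z <= z1. Returns cbind(tin, tout); empty interval where tin > tout.
cylinder_interval <- function(o, d, R, z0, z1) {
  a <- d[, 1]^2 + d[, 2]^2
  b <- o[, 1] * d[, 1] + o[, 2] * d[, 2]
  cc <- o[, 1]^2 + o[, 2]^2 - R^2
  # side-surface interval
  axial <- a < 1e-24
  disc <- b * b - a * cc
  s <- sqrt(pmax(disc, 0))
  t1 <- (-b - s) / ifelse(axial, 1, a)
  t2 <- (-b + s) / ifelse(axial, 1, a)
  inside_r <- cc <= 0
  t1[axial] <- ifelse(inside_r[axial], -Inf, Inf)
  t2[axial] <- ifelse(inside_r[axial], Inf, -Inf)
  hit <- !axial & disc <= 0
  t1[hit] <- Inf
  t2[hit] <- -Inf
  # z-slab interval
  dz <- d[, 3]
  flat <- abs(dz) < 1e-24
  za <- (z0 - o[, 3]) / ifelse(flat, 1, dz)
  zb <- (z1 - o[, 3]) / ifelse(flat, 1, dz)
  zin <- pmin(za, zb)
  zout <- pmax(za, zb)
  inside_z <- o[, 3] >= z0 & o[, 3] <= z1
  zin[flat] <- ifelse(inside_z[flat], -Inf, Inf)
  zout[flat] <- ifelse(inside_z[flat], Inf, -Inf)
  cbind(pmax(t1, zin), pmin(t2, zout))
}

# Parameter interval inside the axis-aligned box [lo, hi] (3-vectors).
box_interval <- function(o, d, lo, hi) {
  tin <- rep(-Inf, nrow(o)); tout <- rep(Inf, nrow(o))
  for (j in 1:3) {
    dj <- d[, j]
    flat <- abs(dj) < 1e-24
    ta <- (lo[j] - o[, j]) / ifelse(flat, 1, dj)
    tb <- (hi[j] - o[, j]) / ifelse(flat, 1, dj)
    lo_t <- pmin(ta, tb); hi_t <- pmax(ta, tb)
    inside <- o[, j] >= lo[j] & o[, j] <= hi[j]
    lo_t[flat] <- ifelse(inside[flat], -Inf, Inf)
    hi_t[flat] <- ifelse(inside[flat], Inf, -Inf)
    tin <- pmax(tin, lo_t); tout <- pmin(tout, hi_t)
  }
  cbind(tin, tout)
}

# Ordered forward milestones for chamber scenes: cumulative boundary
# parameters (m1..m5) such that segment regions are fixed as
# [0,m1] ambient, [m1,m2] wall, [m2,m3] cavity, [m3,m4] wall,
# [m4,m5] ambient, escape beyond m5. Zero-length segments encode missed
# shells; works for origins in any region inside the ambient sphere.
chamber_milestones <- function(o, d, inner, outer, ambient_r) {
  to <- sphere_ts(o, d, outer)
  ti <- sphere_ts(o, d, inner)
  ta <- sphere_ts(o, d, ambient_r)
  b <- rowSums(o * d)
  # closest-approach fallback collapses missed shells to zero-length segs
  miss_o <- is.na(to[, 1])
  to[miss_o, 1] <- -b[miss_o]; to[miss_o, 2] <- -b[miss_o]
  miss_i <- is.na(ti[, 1])
  ti[miss_i, 1] <- -b[miss_i]; ti[miss_i, 2] <- -b[miss_i]
  m5 <- pmax(ta[, 2], 0)
  m <- cbind(to[, 1], ti[, 1], ti[, 2], to[, 2], m5)
  m[m < 0] <- 0
  # enforce ordering (numerically safe cummax across the 5 columns)
  for (j in 2:5) m[, j] <- pmax(m[, j], m[, j - 1])
  pmin(m, m5)
}

# Ordered forward milestones for phantom scenes: [0,m1] body, [m1,m2]
# cavity, [m2,m3] body, escape beyond m3, for origins inside the phantom.
phantom_milestones <- function(o, d, phantom) {
  body <- cylinder_interval(o, d, phantom$radius, 0, phantom$height)
  cav <- cylinder_interval(o, d, phantom$cavity_radius, 0, phantom$height)
  m3 <- pmax(body[, 2], 0)
  empty <- cav[, 1] > cav[, 2]
  c1 <- ifelse(empty, 0, cav[, 1])
  c2 <- ifelse(empty, 0, cav[, 2])
  m <- cbind(c1, c2, m3)
  m[m < 0] <- 0
  m[, 2] <- pmax(m[, 2], m[, 1])
  pmin(m, m3)
}

# --- user-facing geometry operations ------------------------------------

#' Distance to the first material boundary along a ray
#'
#' Traces the ray through a chamber or phantom scene and reports the smallest
#' positive distance at which the material region changes, together with the
#' region labels on both sides. Rays that never meet a boundary return
#' `Inf` with `region_after = "escape"`. Chamber scenes use regions
#' `ambient`/`wall`/`cavity` (the ambient region is unbounded for this
#' query); phantom scenes use `outside`/`body`/`cavity`.
#'
#' @param scene an `irk_chamber` or `irk_phantom`.
#' @param r an [ray()].
#' @return A list with `distance`, `region_before`, `region_after`.
#' @export
first_boundary_distance <- function(scene, r) {
  stopifnot(inherits(r, "irk_ray"))
  o <- matrix(r$origin, 1); d <- matrix(r$direction, 1)
  eps <- 1e-9
  if (inherits(scene, "irk_chamber")) {
    cand <- c(sphere_ts(o, d, scene$inner_radius),
              sphere_ts(o, d, scene$outer_radius))
    cand <- cand[!is.na(cand) & cand > eps]
    reg <- function(p) {
      rr <- sqrt(sum(p^2))
      if (rr < scene$inner_radius) "cavity"
      else if (rr < scene$outer_radius) "wall" else "ambient"
    }
  } else if (inherits(scene, "irk_phantom")) {
    cand <- c(cylinder_interval(o, d, scene$radius, 0, scene$height),
              cylinder_interval(o, d, scene$cavity_radius, 0, scene$height))
    cand <- cand[is.finite(cand) & cand > eps]
    reg <- function(p) locate(scene, p)
  } else {
    abort("scene must be an irk_chamber or irk_phantom")
  }
  before <- reg(r$origin + eps * r$direction)
  if (length(cand) == 0) {
    return(list(distance = Inf, region_before = before,
                region_after = "escape"))
  }
  t0 <- min(cand)
  after <- reg(r$origin + (t0 + eps) * r$direction)
  list(distance = t0, region_before = before, region_after = after)
}

#' Wall path length before first cavity entry
#'
#' Geometric path length through the chamber wall traversed by a ray
#' (originating outside the chamber) before it first enters the cavity; 0 if
#' the cavity is never entered. This is the thickness `t` whose optical depth
#' enters the attenuation unfolding weight `exp(+mu t)` for unscattered
#' photons.
#'
#' @inheritParams first_boundary_distance
#' @param chamber an `irk_chamber`.
#' @return Length in cm.
#' @export
wall_entry_path <- function(chamber, r) {
  stopifnot(inherits(r, "irk_ray"))
  o <- matrix(r$origin, 1); d <- matrix(r$direction, 1)
  if (sqrt(sum(r$origin^2)) < chamber$outer_radius) {
    abort("wall_entry_path() expects a ray originating outside the chamber")
  }
  ti <- sphere_ts(o, d, chamber$inner_radius)
  if (is.na(ti[1, 1]) || ti[1, 1] <= 0) return(0)
  to <- sphere_ts(o, d, chamber$outer_radius)
  max(0, ti[1, 1] - to[1, 1])
}

#' Chord length of a ray through the chamber cavity
#'
#' @inheritParams wall_entry_path
#' @return Length in cm (0 if the cavity is missed).
#' @export
cavity_chord <- function(chamber, r) {
  stopifnot(inherits(r, "irk_ray"))
  o <- matrix(r$origin, 1); d <- matrix(r$direction, 1)
  ti <- sphere_ts(o, d, chamber$inner_radius)
  if (is.na(ti[1, 1])) return(0)
  max(0, ti[1, 2]) - max(0, ti[1, 1])
}

#' Classify a point in a phantom scene
#'
#' Region classification for the cylindrical phantom (axis along z, base at
#' z = 0): `outside`, `body`, or `cavity`. Boundary points resolve to the
#' denser adjacent region (the body).
#'
#' @param scene an `irk_phantom`.
#' @param point numeric length-3, cm.
#' @return One of `"outside"`, `"body"`, `"cavity"`.
#' @export
locate <- function(scene, point) {
  stopifnot(inherits(scene, "irk_phantom"), length(point) == 3)
  rr <- sqrt(point[1]^2 + point[2]^2)
  z <- point[3]
  if (rr > scene$radius || z < 0 || z > scene$height) return("outside")
  if (rr < scene$cavity_radius && z > 0 && z < scene$height) return("cavity")
  "body"
}
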