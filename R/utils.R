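# internal helpers shared by the samplers and transport engines

# Evaluate a function under a locally-seeded RNG stream, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the global stream
# untouched (and advances it).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive reproducible 31-bit sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_local_seed(seed, sample.int(.Machine$integer.max, n))
}

# n unit vectors isotropic on the sphere (matrix n x 3)
isotropic_directions <- function(n) {
  mu <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - mu^2))
  cbind(s * cos(phi), s * sin(phi), mu)
}

# n unit vectors uniform in the cone mu >= mu_min about +z
cone_directions <- function(n, mu_min) {
  mu <- runif(n, mu_min, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - mu^2))
  cbind(s * cos(phi), s * sin(phi), mu)
}

# Rotate local scattering directions (cos_theta, phi uniform) into the frame
# of incident directions d (n x 3, unit). Returns n x 3 unit matrix.
rotate_directions <- function(d, cos_theta, phi = NULL) {
  n <- nrow(d)
  if (is.null(phi)) phi <- runif(n, 0, 2 * pi)
  sin_theta <- sqrt(pmax(0, 1 - cos_theta^2))
  # orthonormal frame (u, v, d); pick helper axis least aligned with d
  hx <- abs(d[, 1]) < 0.9
  a <- cbind(ifelse(hx, 1, 0), ifelse(hx, 0, 1), 0)
  u <- cbind(a[, 2] * d[, 3] - a[, 3] * d[, 2],
             a[, 3] * d[, 1] - a[, 1] * d[, 3],
             a[, 1] * d[, 2] - a[, 2] * d[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(d[, 2] * u[, 3] - d[, 3] * u[, 2],
             d[, 3] * u[, 1] - d[, 1] * u[, 3],
             d[, 1] * u[, 2] - d[, 2] * u[, 1])
  ct <- cos(phi) * sin_theta
  st <- sin(phi) * sin_theta
  out <- d * cos_theta + u * ct + v * st
  out / sqrt(rowSums(out^2))
}

# Deterministic Fibonacci-lattice directions covering the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
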