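test_that("bare line list matches the stated Ir-192 emission window", {
  l <- bare_lines()
  expect_equal(max(l$energy), 0.885, tolerance = 1e-3)
  expect_true(all(l$energy < 1))
  expect_true(all(l$energy >= 0.06))
  expect_true(all(is.finite(l$intensity) & l$intensity > 0))
})

transparent_capsule <- function() {
  capsule_spec(core_material = fictitious_material(0),
               capsule_material = fictitious_material(0))
}

test_that("a transparent capsule reproduces the bare line intensities", {
  sp <- attenuated_spectrum(transparent_capsule(), n_axial = 4, n_radial = 2,
                            n_azimuthal = 2)
  l <- bare_lines()
  bin_of <- findInterval(l$energy, c(sp$bin_lo, tail(sp$bin_hi, 1)),
                         rightmost.closed = TRUE)
  expected <- tapply(l$intensity, bin_of, sum)
  expected <- expected / sum(expected)
  got <- sp$fluence[as.integer(names(expected))]
  expect_equal(unname(got), unname(as.numeric(expected)), tolerance = 1e-12)
  expect_equal(sum(sp$fluence), 1, tolerance = 1e-12)
})

test_that("the attenuated spectrum is normalised with support in the line window", {
  sp <- attenuated_spectrum()
  expect_equal(sum(sp$fluence), 1, tolerance = 1e-12)
  occupied <- sp$fluence > 0
  expect_true(all(sp$bin_lo[occupied] >= 0.06 - 1e-12))
  expect_true(all(sp$bin_hi[occupied] <= 0.885 + 5e-3))
})

test_that("the attenuated Ir-192 mean energy is close to 0.4 MeV", {
  sp <- attenuated_spectrum()
  m <- spectrum_mean_energy(sp)
  expect_gt(m, 0.30)
  expect_lt(m, 0.45)
})

test_that("capsule self-absorption hardens the beam", {
  hard <- spectrum_mean_energy(attenuated_spectrum())
  bare <- spectrum_mean_energy(
    attenuated_spectrum(transparent_capsule(), n_axial = 2, n_radial = 1,
                        n_azimuthal = 1))
  expect_gt(hard, bare)
})

test_that("the core quadrature is converged at the default resolution", {
  a <- attenuated_spectrum(n_axial = 32, n_radial = 16, n_azimuthal = 16)
  b <- attenuated_spectrum(n_axial = 64, n_radial = 32, n_azimuthal = 32)
  expect_lt(max(abs(a$fluence - b$fluence)), 2e-4)
})

test_that("a vanishing capsule converges to the bare spectrum", {
  thin <- capsule_spec(core_length = 1e-5, core_diameter = 1e-6,
                       capsule_outer_length = 2e-5,
                       capsule_radial_thickness = 1e-6)
  sp <- attenuated_spectrum(thin, n_axial = 4, n_radial = 2, n_azimuthal = 2)
  ref <- attenuated_spectrum(transparent_capsule(), n_axial = 4,
                             n_radial = 2, n_azimuthal = 2)
  expect_equal(sp$fluence, ref$fluence, tolerance = 1e-4)
})

test_that("spectrum construction and mean energy handle simple cases", {
  s1 <- spectrum(c(0.35, 0.45), 1)
  expect_equal(spectrum_mean_energy(s1), 0.40)
  s2 <- spectrum(c(0.1, 0.3, 0.5, 0.7), c(1, 0, 1))
  expect_equal(spectrum_mean_energy(s2), 0.4)
  expect_error(spectrum(c(0.1, 0.2), -1), "non-negative")
  expect_error(spectrum(c(0.1, 0.2), 0), "positive")
  expect_error(spectrum(c(0.2, 0.1), 1), "increasing")
})

test_that("energy sampling follows the bin fluences and is reproducible", {
  s1 <- spectrum(c(0.35, 0.45), 1)
  set.seed(2)
  x <- sample_energy(s1, 1000)
  expect_true(all(x >= 0.35 & x <= 0.45))
  sp <- spectrum(c(0.1, 0.2, 0.3, 0.4), c(0.5, 0.2, 0.3))
  set.seed(3)
  n <- 1e5
  x <- sample_energy(sp, n)
  counts <- table(cut(x, c(0.1, 0.2, 0.3, 0.4)))
  for (i in 1:3) {
    p <- sp$fluence[i]
    expect_lt(abs(counts[[i]] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
  set.seed(99)
  a <- sample_energy(sp, 500)
  set.seed(99)
  b <- sample_energy(sp, 500)
  expect_identical(a, b)
})

test_that("spectra round-trip through CSV", {
  sp <- attenuated_spectrum(n_axial = 4, n_radial = 2, n_azimuthal = 2)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$fluence, sp$fluence, tolerance = 1e-12)
  expect_equal(back$bin_lo, sp$bin_lo)
})

test_that("capsule transmission is unity for transparent materials and below one otherwise", {
  n <- 10
  o <- matrix(0, n, 3)
  d <- cbind(1, 0, matrix(0, n, 1))
  tt <- capsule_transmission(o, d, rep(0.4, n), transparent_capsule())
  expect_equal(tt, rep(1, n))
  tr <- capsule_transmission(o, d, rep(0.4, n), capsule_spec())
  expect_true(all(tr < 1 & tr > 0))
  # end-on emission crosses far more material than lateral emission
  dz <- cbind(matrix(0, n, 1), 0, 1)
  tz <- capsule_transmission(o, dz, rep(0.4, n), capsule_spec())
  expect_true(all(tz < tr))
})
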