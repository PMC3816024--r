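test_that("interpolation is exact at every grid point of every packaged table", {
  for (nm in list_materials()) {
    m <- load_material(nm)
    expect_equal(attenuation_coefficient(m, m$energy_grid), m$mu_over_rho,
                 tolerance = 1e-12, info = nm)
    expect_equal(energy_absorption_coefficient(m, m$energy_grid),
                 m$muen_over_rho, tolerance = 1e-12, info = nm)
  }
})

test_that("log-log interpolation matches an independent oracle off-grid", {
  # independent arithmetic straight from the shipped CSV rows bracketing
  # 0.35 MeV (0.3 and 0.4 MeV) for graphite
  csv <- read.csv(system.file("extdata", "materials", "graphite.csv",
                              package = "irkwall"))
  lo <- csv[csv$energy == 0.3, ]
  hi <- csv[csv$energy == 0.4, ]
  wgt <- (log(0.35) - log(0.3)) / (log(0.4) - log(0.3))
  oracle <- exp(log(lo$mu_over_rho) +
                  wgt * (log(hi$mu_over_rho) - log(lo$mu_over_rho)))
  g <- load_material("graphite")
  expect_equal(attenuation_coefficient(g, 0.35), oracle, tolerance = 1e-12)
  # value fixed by the embedded table (frozen from the oracle above)
  expect_equal(attenuation_coefficient(g, 0.35), 0.10048, tolerance = 1e-4)
  expect_equal(attenuation_coefficient(g, 0.4), 0.09546, tolerance = 1e-12)
})

test_that("graphite mu/rho decreases monotonically over 0.1-1.25 MeV", {
  g <- load_material("graphite")
  e <- seq(0.1, 1.25, by = 0.05)
  expect_true(all(diff(attenuation_coefficient(g, e)) < 0))
  expect_gt(attenuation_coefficient(g, 0.3), attenuation_coefficient(g, 1.0))
})

test_that("energy absorption never exceeds attenuation and fractions stay in [0,1]", {
  set.seed(42)
  e <- runif(200, 0.011, 1.49)
  for (nm in list_materials()) {
    m <- load_material(nm)
    expect_true(all(energy_absorption_coefficient(m, e) <=
                      attenuation_coefficient(m, e) * (1 + 1e-9)), info = nm)
    pf <- photoelectric_fraction_at(m, e)
    expect_true(all(pf >= 0 & pf <= 1), info = nm)
  }
})

test_that("queries outside the table raise errors naming the bounds", {
  g <- load_material("graphite")
  expect_error(attenuation_coefficient(g, 0.005), "0\\.01")
  expect_error(attenuation_coefficient(g, 2.0), "1\\.5")
  expect_error(energy_absorption_coefficient(g, 0.001), "range")
})

test_that("fictitious materials give their constants and closed-form behaviour", {
  m <- fictitious_material(0.1, photo_fraction = 0.5, density = 2)
  set.seed(1)
  e <- runif(20, 0.002, 9)
  expect_equal(attenuation_coefficient(m, e), rep(0.1, 20))
  expect_equal(energy_absorption_coefficient(m, e), rep(0.05, 20))
  # equal tables mean equal coefficients
  m2 <- fictitious_material(0.3, photo_fraction = 1)
  expect_equal(energy_absorption_coefficient(m2, e),
               attenuation_coefficient(m2, e))
  # transparent medium has vanishing coefficients
  v <- fictitious_material(0)
  expect_equal(attenuation_coefficient(v, 0.4), 0)
})

test_that("interaction branching follows the photoelectric fraction", {
  set.seed(7)
  pure_sc <- fictitious_material(0.5, photo_fraction = 0)
  expect_true(all(sample_interaction(pure_sc, rep(0.4, 500)) == "incoherent"))
  pure_ab <- fictitious_material(0.5, photo_fraction = 1)
  expect_true(all(sample_interaction(pure_ab, rep(0.4, 500)) == "photoelectric"))
  frac <- fictitious_material(0.5, photo_fraction = 0.3)
  n <- 1e5
  obs <- mean(sample_interaction(frac, rep(0.4, n)) == "photoelectric")
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(obs - 0.3), 3 * se)
})

test_that("invalid material definitions are rejected", {
  expect_error(material("m", -1, c(0.1, 1), c(1, 1), c(1, 1), c(0, 0)),
               "density")
  expect_error(material("m", 1, c(1, 0.1), c(1, 1), c(1, 1), c(0, 0)),
               "increasing")
  expect_error(material("m", 1, c(0.1, 1), c(1, 1), c(2, 2), c(0, 0)),
               "muen")
  expect_error(material("m", 1, c(0.1, 1), c(1, 1), c(1, 1), c(0, 2)),
               "photoelectric")
  expect_error(fictitious_material(-0.1), "mu_const")
  expect_error(fictitious_material(0.1, photo_fraction = 1.5), "photo")
})

test_that("user CSVs round-trip through register_material_csv", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(energy = c(0.01, 0.1, 1), mu_over_rho = c(1, 0.5, 0.2),
                   muen_over_rho = c(0.8, 0.3, 0.1),
                   photoelectric_fraction = c(0.9, 0.4, 0.1))
  write.csv(df, path, row.names = FALSE)
  m <- register_material_csv(path, density = 2.5)
  expect_equal(m$density, 2.5)
  expect_equal(attenuation_coefficient(m, 0.1), 0.5)
  bad <- tempfile(fileext = ".csv")
  write.csv(df[, 1:2], bad, row.names = FALSE)
  expect_error(register_material_csv(bad, density = 1), "columns")
})
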