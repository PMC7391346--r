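test_that("an absorbing transition matrix keeps the chain in its start state", {
  g <- diag(3)
  cfg <- simConfig(n_intervals = 50, gamma = g, delta = c(1, 0, 0), seed = 4)
  set.seed(4)
  tr <- simulateHMMTrack(cfg)
  expect_true(all(tr$states == 1))
})

test_that("empirical transition and stationary frequencies match the chain", {
  cfg <- simConfig(n_intervals = 1e5, seed = 5)
  set.seed(5)
  tr <- simulateHMMTrack(cfg)
  s <- tr$states
  # self-transition frequency of the transit state
  from1 <- which(s[-length(s)] == 1)
  expect_equal(mean(s[from1 + 1] == 1), 0.86, tolerance = 0.01 / 0.86)
  # stationary distribution against the left eigenvector
  pi0 <- stationaryDistribution(cfg$gamma)
  emp <- tabulate(s, 3) / length(s)
  expect_true(all(abs(emp - pi0) < 0.01))
})

test_that("ellipse statistics match the configured error model", {
  # the log-normal is parameterized to hit the configured median and mean
  # exactly: meanlog = log(median), sdlog^2 = 2 log(mean/median)
  sdlog <- sqrt(2 * log(14198 / 4637))
  expect_equal(4637 * exp(sdlog^2 / 2), 14198, tolerance = 1e-12)
  # Monte-Carlo check of the sampled axes (heavy-tailed: CV ~ 2.9, so the
  # sample size must be large for a 5% check on the mean)
  cfg <- simConfig(n_intervals = 4000, fixes_per_interval = 25, seed = 6)
  set.seed(6)
  tr <- simulateHMMTrack(cfg)
  fx <- applyArgosError(tr, cfg)
  expect_gt(nrow(fx), 90000)
  expect_equal(mean(fx$semi_major_m), 14198, tolerance = 0.05)
  expect_equal(median(fx$semi_major_m), 4637, tolerance = 0.05)
  expect_true(all(fx$semi_minor_m <= fx$semi_major_m))
  expect_true(all(fx$orientation_deg >= 0 & fx$orientation_deg < 180))
})

test_that("zero-size ellipses give error-free fixes on the true track", {
  cfg <- simConfig(n_intervals = 30, ellipse_major_mean = 0, seed = 7)
  set.seed(7)
  tr <- simulateHMMTrack(cfg)
  fx <- applyArgosError(tr, cfg)
  xy <- lonlatToKm(fx$lon, fx$lat, cfg$centre)
  px <- approx(tr$times, tr$positions[, 1], xout = fx$time)$y
  py <- approx(tr$times, tr$positions[, 2], xout = fx$time)$y
  expect_equal(xy[, 1], px, tolerance = 1e-6)
  expect_equal(xy[, 2], py, tolerance = 1e-6)
  expect_true(all(fx$semi_major_m == 0))
})

test_that("displacement covariance matches the ellipse-implied covariance", {
  # constant ellipse, many fixes: Monte-Carlo covariance of displacements
  # against the closed-form rotation result
  cfg <- simConfig(n_intervals = 1, fixes_per_interval = 10000,
                   ellipse_major_median = 10000, ellipse_major_mean = 10000,
                   ellipse_axis_ratio = 0.4, ellipse_orient_sd = 1e-9,
                   ellipse_orient_mean = 30, seed = 8)
  set.seed(8)
  tr <- simulateHMMTrack(cfg)
  fx <- applyArgosError(tr, cfg)
  xy <- lonlatToKm(fx$lon, fx$lat, cfg$centre)
  px <- approx(tr$times, tr$positions[, 1], xout = fx$time)$y
  py <- approx(tr$times, tr$positions[, 2], xout = fx$time)$y
  d <- cbind(xy[, 1] - px, xy[, 2] - py)
  S <- ellipseToCov(10000, 4000, 30) / 1e6
  expect_equal(var(d[, 1]), S[1, 1], tolerance = 0.05)
  expect_equal(var(d[, 2]), S[2, 2], tolerance = 0.05)
  expect_equal(cov(d[, 1], d[, 2]), S[1, 2], tolerance = 0.1)
})

test_that("dives, profiles and haul-outs respect the tag conventions", {
  cfg <- simConfig(n_animals = 1, n_intervals = 200, seed = 9)
  set.seed(9)
  tr <- simulateHMMTrack(cfg)
  aux <- simulateDivesTemps(tr, cfg)
  # one dive record per generated count; zero-count intervals have none
  expect_equal(nrow(aux$dives), sum(tr$obs$n_dives))
  expect_true(all(aux$dives$max_depth_m >= 4))
  expect_true(all(aux$dives$end > aux$dives$start))
  expect_equal(nrow(aux$profiles), 17 * nrow(aux$dives))
  expect_true(all(aux$profiles$depth_m >= 0))
  expect_true(all(aux$profiles$temp_C >= -5 & aux$profiles$temp_C <= 35))
  # haul-outs only during transit intervals, >= 5 min
  expect_true(all(aux$haulouts$end - aux$haulouts$start >= 300))
  iv <- findInterval(aux$haulouts$start, tr$times)
  expect_true(all(tr$states[iv] == 1))
})

test_that("noise-free surface temperature equals base + seasonal term", {
  cfg <- simConfig(n_animals = 1, n_intervals = 50, temp_noise_sd = 0,
                   temp_lapse = 0, seed = 10)
  set.seed(10)
  tr <- simulateHMMTrack(cfg)
  aux <- simulateDivesTemps(tr, cfg)
  expected <- cfg$temp_base + cfg$temp_seasonal_amp *
    sin(2 * pi * aux$profiles$dive_start / (365.25 * 86400))
  expect_equal(aux$profiles$temp_C, expected, tolerance = 1e-9)
})

test_that("island bathymetry has the closed-form coastline radius", {
  # extent wide enough that the corners reach the abyssal floor
  cfg <- simConfig(bathy_halfwidth_deg = 6, bathy_cellsize_deg = 0.05)
  grid <- makeBathymetryIsland(cfg)
  ctrIdx <- c(which.min(abs(grid$lon - cfg$centre[1])),
              which.min(abs(grid$lat - cfg$centre[2])))
  expect_gt(grid$z[ctrIdx[1], ctrIdx[2]], 0)           # centre above sea level
  expect_equal(grid$z[1, 1], cfg$bathy_floor_m)        # corners at the floor
  # zero crossing along the eastward lon axis at radius peak/slope
  rowZ <- grid$z[, ctrIdx[2]]
  east <- grid$lon > cfg$centre[1]
  zc <- grid$lon[east][which(rowZ[east] < 0)[1]]       # first sea cell east
  rKm <- geosphere::distGeo(cfg$centre, c(zc, cfg$centre[2])) / 1000
  rTheory <- cfg$bathy_peak_m / cfg$bathy_slope_m_per_km
  cellKm <- 0.05 * 111.32 * cos(cfg$centre[2] * pi / 180)
  expect_lt(abs(rKm - rTheory), cellKm + 1e-9)
})

test_that("dataset generation is deterministic in (config, seed)", {
  cfg <- simConfig(n_animals = 2, n_intervals = 25, seed = 12)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(d1$argos, d2$argos)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$profiles, d2$profiles)
  d3 <- simulateDataset(simConfig(n_animals = 2, n_intervals = 25, seed = 13))
  expect_false(identical(d1$argos, d3$argos))
})
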