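test_that("ellipse covariance handles isotropy, axis alignment and rotation", {
  expect_equal(ellipseToCov(100, 100, 73), diag(1e4, 2))
  expect_equal(ellipseToCov(200, 100, 0), diag(c(4e4, 1e4)))
  S <- ellipseToCov(200, 100, 30)
  ev <- eigen(S)
  expect_equal(sort(ev$values), c(100^2, 200^2))
  # major axis direction at 30 degrees from east
  v <- ev$vectors[, which.max(ev$values)]   # sign is arbitrary: reduce mod pi
  expect_equal(atan2(v[2], v[1]) %% pi, 30 * pi / 180, tolerance = 1e-10)
  # north convention: 30 deg from north = 60 deg from east
  Sn <- ellipseToCov(200, 100, 30, convention = "north")
  expect_equal(Sn, ellipseToCov(200, 100, 60), tolerance = 1e-10)
  expect_error(ellipseToCov(100, 200, 0), "exceeds")
})

test_that("Kalman likelihood equals the brute-force joint Gaussian density", {
  beta <- 0.4; sigma <- 1.5
  times <- c(0, 2.3, 7.1)
  errCov <- list(diag(c(0.5, 0.3)), matrix(c(0.4, 0.1, 0.1, 0.6), 2),
                 diag(c(0.2, 0.2)))
  x0 <- c(1, 0, -2, 0)
  P0 <- diag(c(2, 1, 2, 1))
  set.seed(21)
  z <- matrix(rnorm(6, sd = 2), 3, 2)
  flt <- moveseg:::ctcrwFilter(times, z, errCov, beta, sigma, x0, P0)
  jg <- oracleCtcrwObsGaussian(beta, sigma, times, errCov, x0, P0)
  llOracle <- oracleDmvnorm(as.vector(t(z)), jg$mean, jg$cov)
  expect_equal(flt$loglik, llOracle, tolerance = 1e-8)

  # and on a 4-fix problem with different parameters
  times <- c(0, 1, 4, 9.5)
  errCov <- rep(list(diag(c(0.8, 0.8))), 4)
  z <- matrix(rnorm(8, sd = 3), 4, 2)
  flt <- moveseg:::ctcrwFilter(times, z, errCov, 0.9, 0.7, x0, P0)
  jg <- oracleCtcrwObsGaussian(0.9, 0.7, times, errCov, x0, P0)
  expect_equal(flt$loglik,
               oracleDmvnorm(as.vector(t(z)), jg$mean, jg$cov),
               tolerance = 1e-8)
})

test_that("CTCRW parameters are recovered from a long simulated track", {
  set.seed(22)
  beta <- 0.5; sigma <- 2
  times <- cumsum(c(0, rexp(1999, 1 / 2)))      # irregular, ~2 h apart
  s <- oracleCtcrwSimulate(beta, sigma, times)
  err <- 0.5                                     # 500 m circular 1-sigma
  z <- s[, c(1, 3)] + matrix(rnorm(2 * length(times), 0, err),
                             ncol = 2)
  ll <- kmToLonlat(z[, 1], z[, 2])
  fixes <- data.frame(animal_id = "A", time = times * 3600,
                      lon = ll[, 1], lat = ll[, 2],
                      semi_major_m = err * 1000, semi_minor_m = err * 1000,
                      orientation_deg = 0)
  fit <- fitCTCRW(fixes)
  expect_equal(fit$beta, beta, tolerance = 0.15)
  expect_equal(fit$sigma, sigma, tolerance = 0.15)
})

test_that("smoothed means pass through dense error-free fixes", {
  set.seed(23)
  times <- seq(0, 60, by = 6)                   # fixes exactly on the grid
  s <- oracleCtcrwSimulate(0.3, 1.2, times)
  ll <- kmToLonlat(s[, 1], s[, 3])
  fixes <- data.frame(animal_id = "A", time = times * 3600,
                      lon = ll[, 1], lat = ll[, 2],
                      semi_major_m = 1e-3, semi_minor_m = 1e-3,
                      orientation_deg = 0)
  params <- structure(list(beta = 0.3, sigma = 1.2, centre = studyCentre(),
                           scale = 1), class = "ctcrwParams")
  tr <- predictRegular(params, fixes, interval_h = 6)
  expect_equal(tr$x_km, s[, 1], tolerance = 1e-4)
  expect_equal(tr$y_km, s[, 3], tolerance = 1e-4)
})

test_that("smoother variance peaks at observation-free midpoints", {
  set.seed(24)
  times <- seq(0, 96, by = 12)                  # fixes every 12 h, 6-h grid
  s <- oracleCtcrwSimulate(0.3, 1.2, times)
  ll <- kmToLonlat(s[, 1], s[, 3])
  fixes <- data.frame(animal_id = "A", time = times * 3600,
                      lon = ll[, 1], lat = ll[, 2],
                      semi_major_m = 2000, semi_minor_m = 2000,
                      orientation_deg = 0)
  params <- structure(list(beta = 0.3, sigma = 1.2, centre = studyCentre(),
                           scale = 1), class = "ctcrwParams")
  tr <- predictRegular(params, fixes, interval_h = 6)
  atFix <- seq(1, nrow(tr), by = 2)             # grid points with a fix
  mid <- seq(2, nrow(tr) - 1, by = 2)           # observation-free midpoints
  for (m in mid) {
    expect_gte(tr$var_x[m], min(tr$var_x[c(m - 1, m + 1)]) - 1e-9)
    expect_gte(tr$var_y[m], min(tr$var_y[c(m - 1, m + 1)]) - 1e-9)
  }
  expect_true(all(diff(tr$time) == 6 * 3600))
})

test_that("smoother means match the conditional-Gaussian formula on 4 fixes", {
  set.seed(25)
  beta <- 0.6; sigma <- 1.1
  fixT <- c(0, 5, 13, 18)                        # irregular fixes
  s <- oracleCtcrwSimulate(beta, sigma, fixT)
  errCov <- rep(list(diag(c(0.5, 0.5))), 4)
  z <- s[, c(1, 3)] + matrix(rnorm(8, 0, sqrt(0.5)), ncol = 2)
  ll <- kmToLonlat(z[, 1], z[, 2])
  fixes <- data.frame(animal_id = "A", time = fixT * 3600,
                      lon = ll[, 1], lat = ll[, 2],
                      semi_major_m = sqrt(0.5) * 1000,
                      semi_minor_m = sqrt(0.5) * 1000, orientation_deg = 0)
  params <- structure(list(beta = beta, sigma = sigma, centre = studyCentre(),
                           scale = 1), class = "ctcrwParams")
  tr <- predictRegular(params, fixes, interval_h = 6)
  # oracle: joint Gaussian over the union timeline, conditioned on the fixes
  allT <- sort(unique(c(fixT, seq(0, 18, by = 6))))
  prep <- moveseg:::ctcrwPrepare(fixes, studyCentre(), 1)
  x0 <- c(prep$xy[1, 1], 0, prep$xy[1, 2], 0)
  P0 <- moveseg:::ctcrwInit(beta, sigma, prep$xy[1, ], prep$errCov[[1]])
  jt <- oracleCtcrwJoint(beta, sigma, allT, x0, P0)
  obsIdx <- match(fixT, allT)
  Hrows <- c(rbind(4 * (obsIdx - 1) + 1, 4 * (obsIdx - 1) + 3))
  R <- diag(rep(0.5, 8))
  Coo <- jt$cov[Hrows, Hrows] + R
  gridIdx <- match(seq(0, 18, by = 6), allT)
  qRows <- c(rbind(4 * (gridIdx - 1) + 1, 4 * (gridIdx - 1) + 3))
  zvec <- as.vector(t(prep$xy))
  condMean <- jt$mean[qRows] +
    jt$cov[qRows, Hrows] %*% solve(Coo, zvec - jt$mean[Hrows])
  expect_equal(as.vector(rbind(tr$x_km, tr$y_km)), as.vector(condMean),
               tolerance = 1e-6)
})

test_that("imputation draws reproduce the smoothing distribution", {
  set.seed(26)
  times <- sort(runif(40, 0, 120))
  s <- oracleCtcrwSimulate(0.4, 1.5, times)
  z <- s[, c(1, 3)] + matrix(rnorm(80, 0, 1), ncol = 2)
  ll <- kmToLonlat(z[, 1], z[, 2])
  fixes <- data.frame(animal_id = "A", time = times * 3600,
                      lon = ll[, 1], lat = ll[, 2],
                      semi_major_m = 1000, semi_minor_m = 1000,
                      orientation_deg = 0)
  params <- structure(list(beta = 0.4, sigma = 1.5, centre = studyCentre(),
                           scale = 1), class = "ctcrwParams")
  tr <- predictRegular(params, fixes, interval_h = 6)
  imp <- drawImputations(params, fixes, nSims = 500, seed = 27)
  # ensemble mean consistent with the smoother mean: standardized deviations
  # behave like standard normals (RMS ~ 1, max over 2 x 40 grid points
  # bounded as an extreme of that many draws)
  zx <- (colMeans(imp$x) - tr$x_km) / sqrt(tr$var_x / 500)
  zy <- (colMeans(imp$y) - tr$y_km) / sqrt(tr$var_y / 500)
  expect_lt(sqrt(mean(c(zx, zy)^2)), 1.5)
  expect_lt(max(abs(c(zx, zy))), 4)
  # per-time ensemble variance close to the smoother variance
  relX <- abs(apply(imp$x, 2, var) - tr$var_x) / pmax(tr$var_x, 1e-6)
  expect_lt(median(relX), 0.15)
  # draws are reproducible from the seed
  imp2 <- drawImputations(params, fixes, nSims = 500, seed = 27)
  expect_identical(imp$x, imp2$x)
})

test_that("filter likelihood is translation invariant and degrades with noise", {
  set.seed(28)
  times <- sort(runif(30, 0, 100))
  s <- oracleCtcrwSimulate(0.5, 1, times)
  z <- s[, c(1, 3)] + matrix(rnorm(60, 0, 0.7), ncol = 2)
  errCov <- rep(list(diag(c(0.49, 0.49))), 30)
  x0 <- c(z[1, 1], 0, z[1, 2], 0)
  P0 <- diag(c(1, 1, 1, 1))
  f1 <- moveseg:::ctcrwFilter(times, z, errCov, 0.5, 1, x0, P0)
  shift <- c(500, -300)
  f2 <- moveseg:::ctcrwFilter(times, sweep(z, 2, -shift), errCov, 0.5, 1,
                              x0 + c(shift[1], 0, shift[2], 0), P0)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  # extra measurement noise lowers the likelihood of the true model
  worse <- replicate(5, {
    zn <- z + matrix(rnorm(60, 0, 3), ncol = 2)
    moveseg:::ctcrwFilter(times, zn, errCov, 0.5, 1,
                          c(zn[1, 1], 0, zn[1, 2], 0), P0)$loglik
  })
  expect_true(all(worse < f1$loglik))
})

test_that("regularization rejects under-determined inputs", {
  fixes <- data.frame(animal_id = "A", time = c(0, 3600), lon = c(14, 14.1),
                      lat = c(38, 38.1), semi_major_m = 100,
                      semi_minor_m = 100, orientation_deg = 0)
  expect_error(fitCTCRW(fixes), "at least 10")
  params <- structure(list(beta = 0.5, sigma = 1, centre = studyCentre(),
                           scale = 1), class = "ctcrwParams")
  fixes10 <- data.frame(animal_id = "A", time = seq(0, 9) * 600,
                        lon = 14 + 1:10 / 100, lat = 38 + 1:10 / 100,
                        semi_major_m = 100, semi_minor_m = 100,
                        orientation_deg = 0)
  expect_error(predictRegular(params, fixes10, interval_h = 6),
               "fewer than 3")
})
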