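test_that("gamma moment bridge is exact and round-trips", {
  expect_equal(gammaMomentsToShapeScale(1, 1), list(shape = 1, scale = 1))
  # the transit step distribution: mean 8.152 km, SD 3.27 km
  b <- gammaMomentsToShapeScale(8.152, 3.27)
  expect_equal(b$shape, 6.215, tolerance = 1e-4)
  expect_equal(b$scale, 1.3116, tolerance = 1e-4)
  m <- gammaShapeScaleToMoments(b$shape, b$scale)
  expect_equal(m$mean, 8.152, tolerance = 1e-12)
  expect_equal(m$sd, 3.27, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    mu <- runif(1, 0.1, 50); s <- runif(1, 0.05, 20)
    b <- gammaMomentsToShapeScale(mu, s)
    expect_equal(b$shape * b$scale, mu, tolerance = 1e-12)
    expect_equal(b$shape * b$scale^2, s^2, tolerance = 1e-12)
  }
  expect_error(gammaMomentsToShapeScale(-1, 1), "positive")
})

test_that("von Mises utilities are self-consistent", {
  # density integrates to 1 and the SD<->kappa bridge round-trips
  for (k in c(0.3, 1, 5)) {
    expect_equal(integrate(dvonmises, -pi, pi, mu = 0.3, kappa = k)$value, 1,
                 tolerance = 1e-6)
    expect_equal(vonMisesSdToKappa(vonMisesKappaToSd(k)), k,
                 tolerance = 1e-6)
  }
  set.seed(42)
  x <- rvonmises(20000, 0.5, 2)
  expect_true(all(x > -pi & x <= pi))
  expect_equal(atan2(mean(sin(x)), mean(cos(x))), 0.5, tolerance = 0.05)
})

test_that("a single-state model reduces to independent stream densities", {
  par <- list(stepMean = 5, stepSd = 2, turnMean = 0, turnKappa = 1,
              diveRate = 4, gamma = matrix(1, 1, 1), delta = 1)
  set.seed(43)
  rec <- data.frame(animal_id = "A", step_km = rgamma(30, 4, 1),
                    turn_rad = runif(30, -pi, pi), n_dives = rpois(30, 4))
  b <- gammaMomentsToShapeScale(5, 2)
  direct <- sum(dgamma(rec$step_km, b$shape, scale = b$scale, log = TRUE)) +
    sum(log(exp(1 * cos(rec$turn_rad)) / (2 * pi * besselI(1, 0)))) +
    sum(dpois(rec$n_dives, 4, log = TRUE))
  expect_equal(forwardLoglik(par, rec), direct, tolerance = 1e-10)
})

test_that("forward likelihood equals exhaustive path enumeration", {
  par <- toyPar2()
  rec <- toyRecords(6, par, seed = 44)
  expect_equal(forwardLoglik(par, rec), oracleLoglik(par, rec),
               tolerance = 1e-10)
  # with missing values in every stream
  rec$turn_rad[1] <- NA; rec$step_km[3] <- NA; rec$n_dives[5] <- NA
  expect_equal(forwardLoglik(par, rec), oracleLoglik(par, rec),
               tolerance = 1e-10)
  # property over random instances with N^T <= 1e5
  set.seed(45)
  for (i in 1:5) {
    N <- sample(2:3, 1)
    Tn <- if (N == 2) sample(4:15, 1) else sample(3:10, 1)
    g <- matrix(rgamma(N * N, 1), N)
    g <- g / rowSums(g)
    d <- rgamma(N, 1); d <- d / sum(d)
    p <- list(stepMean = runif(N, 2, 10), stepSd = runif(N, 0.5, 3),
              turnMean = runif(N, -2, 2), turnKappa = runif(N, 0.1, 3),
              diveRate = runif(N, 0.5, 12), gamma = g, delta = d)
    r <- toyRecords(Tn, p, seed = 100 + i)
    expect_equal(forwardLoglik(p, r), oracleLoglik(p, r), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to a simultaneous state relabeling", {
  par <- toyPar2()
  rec <- toyRecords(12, par, seed = 46)
  perm <- c(2, 1)
  par2 <- list(stepMean = par$stepMean[perm], stepSd = par$stepSd[perm],
               turnMean = par$turnMean[perm], turnKappa = par$turnKappa[perm],
               diveRate = par$diveRate[perm],
               gamma = par$gamma[perm, perm], delta = par$delta[perm])
  expect_equal(forwardLoglik(par, rec), forwardLoglik(par2, rec),
               tolerance = 1e-12)
})

test_that("multi-animal likelihood is the sum of per-animal likelihoods", {
  par <- toyPar2()
  r1 <- toyRecords(5, par, seed = 47, animal_id = "A")
  r2 <- toyRecords(7, par, seed = 48, animal_id = "B")
  expect_equal(forwardLoglik(par, rbind(r1, r2)),
               oracleLoglik(par, r1) + oracleLoglik(par, r2),
               tolerance = 1e-10)
})

test_that("Viterbi matches the exhaustive argmax and handles identity chains", {
  par <- toyPar2()
  fitLike <- c(par, list(nStates = 2))
  rec <- toyRecords(6, par, seed = 49)
  expect_equal(viterbi(fitLike, rec), oracleViterbi(par, rec))
  set.seed(50)
  for (i in 1:3) {
    r <- toyRecords(8, par, seed = 200 + i)
    expect_equal(viterbi(fitLike, r), oracleViterbi(par, r))
  }
  # an identity transition matrix locks the path to one state
  parI <- par; parI$gamma <- diag(2)
  recI <- toyRecords(10, par, seed = 51)
  v <- viterbi(c(parI, list(nStates = 2)), recI)
  expect_equal(length(unique(v)), 1L)
})

test_that("forward-backward marginals match exhaustive enumeration", {
  par <- toyPar2()
  rec <- toyRecords(7, par, seed = 52)
  sp <- stateProbs(c(par, list(nStates = 2)), rec)
  expect_equal(rowSums(sp$probs), rep(1, 7), tolerance = 1e-10)
  expect_equal(sp$probs, oracleMarginals(par, rec), tolerance = 1e-10)
  expect_equal(sp$divingProb, sp$probs[, 2], tolerance = 1e-12)
})

test_that("fitting recovers parameters and is a fixed point of itself", {
  cfg <- simConfig(n_animals = 4, n_intervals = 250, seed = 53)
  ds <- simulateDataset(cfg)
  fit <- fitHMM(ds$truth, nStates = 3, nStarts = 6, seed = 54)
  expect_equal(diag(fit$gamma), c(0.86, 0.80, 0.86), tolerance = 0.06)
  expect_equal(fit$stepMean, cfg$step_mean, tolerance = 0.1)
  expect_equal(fit$diveRate, cfg$dive_rate, tolerance = 0.1)
  # canonical ordering: ascending dive rate
  expect_false(is.unsorted(fit$diveRate))
  # AIC identity and stochastic rows
  expect_identical(fit$aic, -2 * fit$loglik + 2 * fit$nPar)
  expect_equal(rowSums(fit$gamma), rep(1, 3), tolerance = 1e-10)
  expect_equal(sum(fit$delta), 1, tolerance = 1e-10)
  # refit from the optimum returns the same likelihood
  refit <- fitHMM(ds$truth, nStates = 3,
                  initPar = moveseg:::fitPar(fit))
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
  # decoding accuracy on well-separated states
  v <- viterbi(fit, ds$truth)
  expect_gt(mean(v == ds$truth$state), 0.9)
})

test_that("the 3-state model is AIC-preferred on 3-state data", {
  for (s in 1:3) {
    cfg <- simConfig(n_animals = 2, n_intervals = 150, seed = 60 + s)
    ds <- simulateDataset(cfg)
    f3 <- fitHMM(ds$truth, nStates = 3, nStarts = 5, seed = s)
    f2 <- fitHMM(ds$truth, nStates = 2, nStarts = 5, seed = s)
    expect_lt(f3$aic, f2$aic)
  }
})

test_that("Poisson pseudo-residuals use the closed-form mid-P transform", {
  lam <- 3.7
  par <- list(stepMean = 5, stepSd = 2, turnMean = 0, turnKappa = 1,
              diveRate = lam, gamma = matrix(1, 1, 1), delta = 1)
  x <- c(0, 2, 5, 9)
  rec <- data.frame(animal_id = "A", step_km = NA_real_, turn_rad = NA_real_,
                    n_dives = x)
  pr <- pseudoRes(par, rec)
  # direct summation oracle: F(x-1) + 0.5 p(x)
  oracle <- vapply(x, function(xi)
    sum(dpois(seq_len(xi) - 1, lam)) + 0.5 * dpois(xi, lam), numeric(1))
  expect_equal(pnorm(pr$diveRes), oracle, tolerance = 1e-9)
})

test_that("pseudo-residuals are calibrated under the generating model", {
  cfg <- simConfig(n_animals = 1, n_intervals = 4000, seed = 55)
  ds <- simulateDataset(cfg)
  par <- list(stepMean = cfg$step_mean, stepSd = cfg$step_sd,
              turnMean = cfg$turn_mean, turnKappa = cfg$turn_kappa,
              diveRate = cfg$dive_rate, gamma = cfg$gamma, delta = cfg$delta)
  pr <- pseudoRes(par, ds$truth)
  bound <- 2 / sqrt(4000)
  expect_lt(abs(pr$acf["stepRes", 1]), bound)
  expect_lt(abs(pr$acf["diveRes", 1]), bound)
  expect_true(all(pr$shapiroW > 0.99, na.rm = TRUE))
  expect_false(any(pr$degenerate))
})

test_that("a constant stream is flagged as degenerate, not NaN", {
  par <- toyPar2()
  rec <- toyRecords(25, par, seed = 56)
  rec$n_dives <- 5L
  pr <- pseudoRes(c(par, list(nStates = 2)), rec)
  expect_true(pr$degenerate[["n_dives"]])
  expect_false(any(is.nan(pr$diveRes)))
})

test_that("Rubin pooling reproduces hand arithmetic and identical-fit limits", {
  # hand-computed example: Q = (1, 3), U = (0.5, 1.5)
  p <- poolRubin(matrix(c(1, 3), 2, 1), matrix(c(0.5, 1.5), 2, 1))
  expect_identical(p$estimate, 2)
  expect_identical(p$within, 1)
  expect_identical(p$between, 2)
  expect_equal(p$total, 1 + 1.5 * 2, tolerance = 1e-12)
  expect_error(poolRubin(matrix(1, 1, 1)), "at least 2")
})

test_that("pooling identical fits returns them with zero between-variance", {
  cfg <- simConfig(n_animals = 2, n_intervals = 100, seed = 57)
  ds <- simulateDataset(cfg)
  fit <- fitHMM(ds$truth, nStates = 3, nStarts = 4, seed = 58)
  pooled <- poolFits(list(fit, fit, fit))
  expect_equal(pooled$gamma, fit$gamma, tolerance = 1e-12)
  expect_equal(pooled$stepMean, fit$stepMean, tolerance = 1e-12)
  expect_equal(max(pooled$pooled$between), 0, tolerance = 1e-12)
  # label misalignment is detected
  bad <- fit
  bad$diveRate <- rev(bad$diveRate)
  expect_error(poolFits(list(fit, bad)), "misaligned.*2")
})
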