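# Independent oracles used across the suite. These deliberately avoid the
# package's own recursion/filter code paths: likelihoods by exhaustive path
# enumeration or explicit joint-Gaussian construction, densities written out
# directly.

# per-interval emission probability matrix, written independently of
# moveseg's internals
oracleEmissionProbs <- function(par, records) {
  N <- length(par$stepMean)
  Tn <- nrow(records)
  P <- matrix(1, Tn, N)
  for (k in seq_len(N)) {
    shape <- par$stepMean[k]^2 / par$stepSd[k]^2
    scale <- par$stepSd[k]^2 / par$stepMean[k]
    p <- rep(1, Tn)
    ok <- !is.na(records$step_km)
    p[ok] <- p[ok] * dgamma(records$step_km[ok], shape = shape, scale = scale)
    ok <- !is.na(records$turn_rad)
    p[ok] <- p[ok] *
      exp(par$turnKappa[k] * cos(records$turn_rad[ok] - par$turnMean[k])) /
      (2 * pi * besselI(par$turnKappa[k], 0))
    ok <- !is.na(records$n_dives)
    p[ok] <- p[ok] * dpois(records$n_dives[ok], par$diveRate[k])
    P[, k] <- p
  }
  P
}

# all N^T state paths of a single-animal series
oraclePaths <- function(N, Tn) {
  as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
}

oraclePathProb <- function(path, par, P) {
  pr <- par$delta[path[1]] * P[1, path[1]]
  for (t in seq_along(path)[-1])
    pr <- pr * par$gamma[path[t - 1], path[t]] * P[t, path[t]]
  pr
}

# exhaustive-path log-likelihood (one animal)
oracleLoglik <- function(par, records) {
  P <- oracleEmissionProbs(par, records)
  paths <- oraclePaths(length(par$delta), nrow(records))
  log(sum(apply(paths, 1, oraclePathProb, par = par, P = P)))
}

# exhaustive MAP path (one animal)
oracleViterbi <- function(par, records) {
  P <- oracleEmissionProbs(par, records)
  paths <- oraclePaths(length(par$delta), nrow(records))
  pr <- apply(paths, 1, oraclePathProb, par = par, P = P)
  as.integer(paths[which.max(pr), ])
}

# exhaustive posterior state marginals (one animal)
oracleMarginals <- function(par, records) {
  P <- oracleEmissionProbs(par, records)
  N <- length(par$delta); Tn <- nrow(records)
  paths <- oraclePaths(N, Tn)
  pr <- apply(paths, 1, oraclePathProb, par = par, P = P)
  pr <- pr / sum(pr)
  out <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) for (k in seq_len(N))
    out[t, k] <- sum(pr[paths[, t] == k])
  out
}

# exact discrete transition/noise of the integrated-OU (CTCRW) model for one
# axis, written from the closed forms (independent of moveseg's internals)
oracleCtcrwAQ <- function(beta, sigma, dt) {
  e1 <- exp(-beta * dt); e2 <- exp(-2 * beta * dt)
  A <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
  q11 <- sigma^2 / beta^2 *
    (dt - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta))
  q12 <- sigma^2 / (2 * beta^2) * (1 - e1)^2
  q22 <- sigma^2 / (2 * beta) * (1 - e2)
  list(A = A, Q = matrix(c(q11, q12, q12, q22), 2, 2))
}

# joint mean/covariance of the stacked 4-D states at the given times
oracleCtcrwJoint <- function(beta, sigma, times_h, x0, P0) {
  n <- length(times_h)
  A4 <- function(dt) {
    b <- oracleCtcrwAQ(beta, sigma, dt)
    A <- matrix(0, 4, 4); A[1:2, 1:2] <- b$A; A[3:4, 3:4] <- b$A
    A
  }
  Q4 <- function(dt) {
    b <- oracleCtcrwAQ(beta, sigma, dt)
    Q <- matrix(0, 4, 4); Q[1:2, 1:2] <- b$Q; Q[3:4, 3:4] <- b$Q
    Q
  }
  means <- matrix(0, n, 4)
  margs <- vector("list", n)
  means[1, ] <- x0; margs[[1]] <- P0
  As <- vector("list", n)
  for (i in 2:n) {
    dt <- times_h[i] - times_h[i - 1]
    As[[i]] <- A4(dt)
    means[i, ] <- As[[i]] %*% means[i - 1, ]
    margs[[i]] <- As[[i]] %*% margs[[i - 1]] %*% t(As[[i]]) + Q4(dt)
  }
  C <- matrix(0, 4 * n, 4 * n)
  for (i in seq_len(n)) {
    C[(4 * i - 3):(4 * i), (4 * i - 3):(4 * i)] <- margs[[i]]
    if (i < n) {
      Cij <- margs[[i]]
      for (j in (i + 1):n) {
        Cij <- Cij %*% t(As[[j]])
        C[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)] <- Cij
        C[(4 * j - 3):(4 * j), (4 * i - 3):(4 * i)] <- t(Cij)
      }
    }
  }
  list(mean = as.vector(t(means)), cov = C)
}

# observation-level joint Gaussian: selects the positions and adds the
# per-fix measurement covariances
oracleCtcrwObsGaussian <- function(beta, sigma, times_h, errCov, x0, P0) {
  jt <- oracleCtcrwJoint(beta, sigma, times_h, x0, P0)
  n <- length(times_h)
  H <- matrix(0, 2 * n, 4 * n)
  for (i in seq_len(n)) {
    H[2 * i - 1, 4 * i - 3] <- 1
    H[2 * i, 4 * i - 1] <- 1
  }
  R <- matrix(0, 2 * n, 2 * n)
  for (i in seq_len(n))
    R[(2 * i - 1):(2 * i), (2 * i - 1):(2 * i)] <- errCov[[i]]
  list(mean = as.vector(H %*% jt$mean),
       cov = H %*% jt$cov %*% t(H) + R)
}

oracleDmvnorm <- function(z, mean, cov) {
  cS <- chol(cov)
  d <- length(z)
  -d / 2 * log(2 * pi) - sum(log(diag(cS))) -
    0.5 * sum(backsolve(cS, z - mean, transpose = TRUE)^2)
}

# simulate an exact CTCRW realization at arbitrary times (for recovery tests)
oracleCtcrwSimulate <- function(beta, sigma, times_h, x0 = c(0, 0, 0, 0)) {
  n <- length(times_h)
  s <- matrix(0, n, 4)
  s[1, ] <- x0
  for (i in 2:n) {
    dt <- times_h[i] - times_h[i - 1]
    b <- oracleCtcrwAQ(beta, sigma, dt)
    A <- matrix(0, 4, 4); A[1:2, 1:2] <- b$A; A[3:4, 3:4] <- b$A
    Q <- matrix(0, 4, 4); Q[1:2, 1:2] <- b$Q; Q[3:4, 3:4] <- b$Q
    s[i, ] <- A %*% s[i - 1, ] + t(chol(Q + diag(1e-14, 4))) %*% rnorm(4)
  }
  s
}

# analytic bivariate-normal density grid (for isopleth/overlap closed forms)
analyticGaussianGrid <- function(mx, my, sdx, sdy, xg, yg) {
  z <- outer(dnorm(xg, mx, sdx), dnorm(yg, my, sdy))
  cellArea <- diff(xg[1:2]) * diff(yg[1:2])
  z <- z / (sum(z) * cellArea)
  structure(list(x = xg, y = yg, z = z, cellArea = cellArea,
                 bandwidth = c(sdx, sdy), nEff = NA),
            class = "densityGrid")
}

# small interval-record fixture for HMM toy tests
toyRecords <- function(Tn, par, seed = 1, animal_id = "T1") {
  set.seed(seed)
  N <- length(par$delta)
  states <- integer(Tn)
  states[1] <- sample.int(N, 1, prob = par$delta)
  for (t in seq_len(Tn - 1))
    states[t + 1] <- sample.int(N, 1, prob = par$gamma[states[t], ])
  shape <- par$stepMean^2 / par$stepSd^2
  scale <- par$stepSd^2 / par$stepMean
  data.frame(
    animal_id = animal_id,
    step_km = rgamma(Tn, shape[states], scale = scale[states]),
    turn_rad = vapply(states, function(k)
      rvonmises(1, par$turnMean[k], par$turnKappa[k]), numeric(1)),
    n_dives = rpois(Tn, par$diveRate[states]),
    stringsAsFactors = FALSE)
}

toyPar2 <- function() {
  list(stepMean = c(8, 3), stepSd = c(3, 1.5),
       turnMean = c(0, 0.2), turnKappa = c(1.5, 0.4),
       diveRate = c(2, 10),
       gamma = matrix(c(0.85, 0.15, 0.2, 0.8), 2, 2, byrow = TRUE),
       delta = c(0.6, 0.4))
}
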