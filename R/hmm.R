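#' Hidden Markov model for movement intervals
#'
#' A 3-state (configurable N >= 2) HMM over three data streams per 6-hr
#' interval: step length (Gamma), turning angle (von Mises) and number of
#' dives (Poisson). Missing stream values contribute likelihood 1 for that
#' stream, so an interval with an undefined turning angle still informs the
#' step and dive streams. Multiple animals are handled as independent series
#' restarted at the initial distribution.
#'
#' @name hmm
NULL

# ---- working <-> natural parameterization ----------------------------------
# step: log mean, log sd per state; turn: (wx, wy) with kappa = |(wx,wy)|,
# mu = atan2(wy, wx); dives: log rate; gamma rows: logits vs the diagonal;
# delta: logits vs state 1.

hmmNpar <- function(N) 5 * N + N * (N - 1) + (N - 1)

hmmPack <- function(par) {
  N <- length(par$stepMean)
  # column r holds row r's off-diagonal logits vs the diagonal
  gEta <- vapply(seq_len(N), function(r)
    log(par$gamma[r, -r] / par$gamma[r, r]), numeric(N - 1))
  c(log(par$stepMean), log(par$stepSd),
    par$turnKappa * cos(par$turnMean), par$turnKappa * sin(par$turnMean),
    log(par$diveRate),
    as.vector(gEta),
    log(par$delta[-1] / par$delta[1]))
}

hmmUnpack <- function(w, N) {
  i <- 0
  take <- function(k) { out <- w[(i + 1):(i + k)]; i <<- i + k; out }
  stepMean <- exp(take(N)); stepSd <- exp(take(N))
  wx <- take(N); wy <- take(N)
  turnKappa <- sqrt(wx^2 + wy^2); turnMean <- atan2(wy, wx)
  diveRate <- exp(take(N))
  gEta <- matrix(take(N * (N - 1)), N - 1, N)
  gamma <- diag(N)
  for (r in seq_len(N)) {
    e <- exp(gEta[, r])
    gamma[r, -r] <- e / (1 + sum(e))
    gamma[r, r] <- 1 / (1 + sum(e))
  }
  dEta <- c(0, take(N - 1))
  delta <- exp(dEta) / sum(exp(dEta))
  list(stepMean = stepMean, stepSd = stepSd, turnMean = turnMean,
       turnKappa = turnKappa, diveRate = diveRate, gamma = gamma,
       delta = delta)
}

# T x N matrix of per-interval emission probabilities (streams multiplied,
# missing values contributing 1)
hmmAllProbs <- function(par, records) {
  N <- length(par$stepMean)
  Tn <- nrow(records)
  ss <- gammaMomentsToShapeScale(par$stepMean, par$stepSd)
  P <- matrix(1, Tn, N)
  for (k in seq_len(N)) {
    p <- rep(1, Tn)
    ok <- !is.na(records$step_km)
    p[ok] <- p[ok] * dgamma(records$step_km[ok], shape = ss$shape[k],
                            scale = ss$scale[k])
    ok <- !is.na(records$turn_rad)
    p[ok] <- p[ok] * dvonmises(records$turn_rad[ok], par$turnMean[k],
                               par$turnKappa[k])
    ok <- !is.na(records$n_dives)
    p[ok] <- p[ok] * dpois(records$n_dives[ok], par$diveRate[k])
    P[, k] <- p
  }
  if (any(!is.finite(P))) {
    bad <- which(!is.finite(P), arr.ind = TRUE)[1, ]
    stop("non-finite emission density at interval ", bad[1],
         ", state ", bad[2])
  }
  P
}

hmmStartIndex <- function(records) {
  id <- as.character(records$animal_id)
  which(!duplicated(id))
}

#' Forward log-likelihood of interval records
#'
#' Scaled forward recursion (log space) summed over animals, each animal's
#' series restarted at the initial distribution.
#'
#' @param par named list of natural parameters: `stepMean`, `stepSd`,
#'   `turnMean`, `turnKappa`, `diveRate` (each length N), `gamma` (N x N
#'   row-stochastic), `delta` (length N).
#' @param records data.frame with columns `animal_id`, `step_km`, `turn_rad`,
#'   `n_dives` (NA = missing), ordered by time within animal.
#' @return log-likelihood (scalar).
#' @export
forwardLoglik <- function(par, records) {
  P <- hmmAllProbs(par, records)
  forwardLogLikC(P, par$gamma, par$delta,
                 as.integer(hmmStartIndex(records)))
}

# data-driven initial values: tertile split on dive counts (the stream that
# orders the states), step moments per tertile
hmmInitPar <- function(records, N) {
  nd <- records$n_dives[!is.na(records$n_dives)]
  st <- records$step_km[!is.na(records$step_km)]
  qs <- quantile(nd, probs = seq(0, 1, length.out = N + 1))
  grp <- cut(records$n_dives, breaks = unique(c(-1, qs[-1])) + 0.5,
             labels = FALSE)
  grp[is.na(grp)] <- 1
  stepMean <- stepSd <- diveRate <- numeric(N)
  for (k in seq_len(N)) {
    sel <- which(grp == k & !is.na(records$step_km))
    stepMean[k] <- if (length(sel) > 3) mean(records$step_km[sel]) else mean(st)
    stepSd[k] <- if (length(sel) > 3) max(sd(records$step_km[sel]), 1e-3)
                 else max(sd(st), 1e-3)
    seld <- which(grp == k & !is.na(records$n_dives))
    diveRate[k] <- if (length(seld)) max(mean(records$n_dives[seld]), 0.05)
                   else max(mean(nd), 0.05) * k
  }
  o <- order(diveRate)
  list(stepMean = stepMean[o], stepSd = stepSd[o],
       turnMean = rep(0, N), turnKappa = rep(1, N),
       diveRate = diveRate[o],
       gamma = matrix(0.1 / (N - 1), N, N) + diag(N) * (0.9 - 0.1 / (N - 1)),
       delta = rep(1 / N, N))
}

hmmRelabel <- function(par) {
  o <- order(par$diveRate)
  list(stepMean = par$stepMean[o], stepSd = par$stepSd[o],
       turnMean = par$turnMean[o], turnKappa = par$turnKappa[o],
       diveRate = par$diveRate[o],
       gamma = par$gamma[o, o, drop = FALSE], delta = par$delta[o])
}

#' Fit the movement HMM by direct likelihood maximization
#'
#' Maximizes the forward log-likelihood over unconstrained working parameters
#' (logs for positive quantities, a Cartesian pair for the angle mean and
#' concentration, multinomial logits for transition-matrix rows and the
#' initial distribution) with `nStarts` perturbed data-driven
#' initializations. Zero step lengths — possible after track regularization —
#' are replaced by half the smallest positive step (the Gamma density has no
#' mass at zero); the replacement count is reported. States are relabeled
#' canonically by ascending Poisson dive rate, so state 1 is "transit"
#' (fewest dives) and state N "high-intensity diving".
#'
#' @param records see [forwardLoglik()].
#' @param nStates number of states N (>= 2; default 3).
#' @param nStarts number of optimizer starts (default 25).
#' @param seed RNG seed for start perturbations.
#' @param initPar optional natural-parameter list used as the sole start
#'   (e.g. when refitting imputations from a pilot fit).
#' @param hessian compute the observed-information variance of the working
#'   parameters (needed for Rubin's-rules pooling with within-imputation
#'   variance).
#' @return object of class `hmmFit`: natural parameters (`stepMean`,
#'   `stepSd`, `stepShape`, `stepScale`, `turnMean`, `turnKappa`,
#'   `diveRate`), `gamma`, `delta`, `loglik`, `aic`, `nPar`, `nStates`,
#'   `stateNames`, working parameters `wpar` (and `wvar` if `hessian`),
#'   per-start log-likelihoods and convergence codes, `nZeroSteps`.
#' @export
fitHMM <- function(records, nStates = 3, nStarts = 25, seed = NULL,
                   initPar = NULL, hessian = FALSE) {
  stopifnot(nStates >= 2)
  need <- c("animal_id", "step_km", "turn_rad", "n_dives")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  records <- as.data.frame(records)
  nZero <- sum(records$step_km == 0, na.rm = TRUE)
  if (nZero > 0) {
    minPos <- min(records$step_km[records$step_km > 0], na.rm = TRUE)
    records$step_km[!is.na(records$step_km) & records$step_km == 0] <- minPos / 2
    message(nZero, " zero step length(s) replaced by ", minPos / 2, " km")
  }
  aInd <- as.integer(hmmStartIndex(records))
  stepV <- as.numeric(records$step_km)
  turnV <- as.numeric(records$turn_rad)
  diveV <- as.numeric(records$n_dives)
  logStep <- suppressWarnings(log(stepV))
  turnCos <- cos(turnV); turnSin <- sin(turnV)
  lgamNd <- lgamma(diveV + 1)
  # large finite penalty (not an error) keeps quasi-Newton line searches
  # away from overflowing working-parameter regions
  negll <- function(w) {
    if (any(!is.finite(w)) || max(abs(w)) > 50) return(1e10)
    par <- hmmUnpack(w, nStates)
    ss <- gammaMomentsToShapeScale(par$stepMean, par$stepSd)
    nll <- nLogLikC(stepV, logStep, turnCos, turnSin, diveV, lgamNd,
                    ss$shape, ss$scale,
                    par$turnMean, par$turnKappa, par$diveRate,
                    par$gamma, par$delta, aInd)
    if (!is.finite(nll)) return(1e10)
    nll
  }
  base <- if (is.null(initPar)) hmmInitPar(records, nStates) else initPar
  starts <- if (is.null(initPar)) nStarts else 1L
  bestVal <- Inf; bestW <- NULL
  startLL <- rep(NA_real_, starts); conv <- rep(NA_integer_, starts)
  for (s in seq_len(starts)) {
    p0 <- base
    if (s > 1) {   # log-normal perturbation of the data-driven moments
      p0$stepMean <- p0$stepMean * exp(rnorm(nStates, 0, 0.3))
      p0$stepSd <- p0$stepSd * exp(rnorm(nStates, 0, 0.3))
      p0$diveRate <- p0$diveRate * exp(rnorm(nStates, 0, 0.3))
      p0$turnKappa <- p0$turnKappa * exp(rnorm(nStates, 0, 0.5))
      p0$turnMean <- wrapAngle(p0$turnMean + rnorm(nStates, 0, 0.5))
    }
    w0 <- hmmPack(p0)
    fit <- tryCatch(
      optim(w0, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    startLL[s] <- -fit$value; conv[s] <- fit$convergence
    if (fit$value < bestVal) { bestVal <- fit$value; bestW <- fit$par }
  }
  if (is.null(bestW))
    stop("all ", starts, " optimizer starts failed; convergence codes: ",
         paste(conv, collapse = ","))
  par <- hmmRelabel(hmmUnpack(bestW, nStates))
  wpar <- hmmPack(par)
  loglik <- -negll(wpar)
  k <- hmmNpar(nStates)
  ss <- gammaMomentsToShapeScale(par$stepMean, par$stepSd)
  out <- list(
    stepMean = par$stepMean, stepSd = par$stepSd,
    stepShape = ss$shape, stepScale = ss$scale,
    turnMean = par$turnMean, turnKappa = par$turnKappa,
    diveRate = par$diveRate,
    gamma = par$gamma, delta = par$delta,
    loglik = loglik, nPar = k, aic = -2 * loglik + 2 * k,
    nStates = nStates,
    stateNames = if (nStates == 3)
      c("transit", "low-intensity diving", "high-intensity diving")
    else paste("state", seq_len(nStates)),
    wpar = wpar, startLoglik = startLL, convergence = conv,
    nZeroSteps = nZero, nObs = nrow(records))
  if (hessian) {
    H <- optimHess(wpar, negll)
    V <- tryCatch(solve(H), error = function(e) matrix(NA, k, k))
    out$wvar <- diag(V)
  }
  class(out) <- "hmmFit"
  out
}

#' @export
print.hmmFit <- function(x, ...) {
  cat("hmmFit:", x$nStates, "states,", x$nObs, "intervals, logLik",
      format(x$loglik, digits = 8), " AIC", format(x$aic, digits = 8), "\n")
  tab <- data.frame(
    state = x$stateNames,
    step_mean_km = round(x$stepMean, 3), step_sd_km = round(x$stepSd, 3),
    turn_mean_rad = round(x$turnMean, 3), turn_kappa = round(x$turnKappa, 3),
    dive_rate = round(x$diveRate, 3))
  print(tab, row.names = FALSE)
  cat("transition matrix:\n")
  print(round(x$gamma, 3))
  invisible(x)
}

#' Viterbi decoding
#'
#' Exact maximum a posteriori state path by dynamic programming, per animal,
#' ties broken toward the lower state index.
#'
#' @param fit an `hmmFit`.
#' @param records interval records (see [forwardLoglik()]).
#' @return integer vector of decoded states, one per record row.
#' @export
viterbi <- function(fit, records) {
  par <- fitPar(fit)
  P <- hmmAllProbs(par, records)
  lP <- log(P); lG <- log(par$gamma); ld <- log(par$delta)
  aInd <- hmmStartIndex(records)
  Tn <- nrow(records); N <- ncol(P)
  states <- integer(Tn)
  bounds <- cbind(aInd, c(aInd[-1] - 1, Tn))
  for (b in seq_len(nrow(bounds))) {
    i0 <- bounds[b, 1]; i1 <- bounds[b, 2]; L <- i1 - i0 + 1
    v <- matrix(-Inf, L, N); bp <- matrix(0L, L, N)
    v[1, ] <- ld + lP[i0, ]
    if (L > 1) for (t in 2:L) {
      for (j in seq_len(N)) {
        cand <- v[t - 1, ] + lG[, j]
        bp[t, j] <- which.max(cand)
        v[t, j] <- cand[bp[t, j]] + lP[i0 + t - 1, j]
      }
    }
    s <- integer(L)
    s[L] <- which.max(v[L, ])
    if (L > 1) for (t in (L - 1):1) s[t] <- bp[t + 1, s[t + 1]]
    states[i0:i1] <- s
  }
  states
}

#' Forward-backward state probabilities
#'
#' Posterior probability of each state per interval, and the merged diving
#' probability P(state 2) + ... + P(state N) used to map general diving
#' activity.
#'
#' @inheritParams viterbi
#' @return list of class `stateSequence`: `probs` (T x N matrix, rows summing
#'   to 1), `divingProb`, `viterbi` (decoded states).
#' @export
stateProbs <- function(fit, records) {
  par <- fitPar(fit)
  P <- hmmAllProbs(par, records)
  aInd <- hmmStartIndex(records)
  Tn <- nrow(P); N <- ncol(P)
  alpha <- matrix(0, Tn, N); beta <- matrix(0, Tn, N)
  scal <- numeric(Tn)
  bounds <- cbind(aInd, c(aInd[-1] - 1, Tn))
  for (b in seq_len(nrow(bounds))) {
    i0 <- bounds[b, 1]; i1 <- bounds[b, 2]
    v <- par$delta * P[i0, ]
    scal[i0] <- sum(v); alpha[i0, ] <- v / scal[i0]
    if (i1 > i0) for (t in (i0 + 1):i1) {
      v <- (alpha[t - 1, ] %*% par$gamma) * P[t, ]
      scal[t] <- sum(v); alpha[t, ] <- v / scal[t]
    }
    beta[i1, ] <- 1
    if (i1 > i0) for (t in (i1 - 1):i0) {
      beta[t, ] <- par$gamma %*% (P[t + 1, ] * beta[t + 1, ]) / scal[t + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  out <- list(probs = post,
              divingProb = rowSums(post[, -1, drop = FALSE]),
              viterbi = viterbi(fit, records))
  class(out) <- "stateSequence"
  out
}

fitPar <- function(fit) {
  if (inherits(fit, "hmmFit"))
    list(stepMean = fit$stepMean, stepSd = fit$stepSd,
         turnMean = fit$turnMean, turnKappa = fit$turnKappa,
         diveRate = fit$diveRate, gamma = fit$gamma, delta = fit$delta)
  else fit
}

#' One-step-ahead pseudo-residuals
#'
#' Forecast-CDF transforms of each observation under the fitted model, per
#' stream, probit-transformed to the normal scale; the discrete dive-count
#' stream uses mid-P residuals F(x-1) + 0.5 p(x). Under a correctly specified
#' model the residuals are approximately iid standard normal; lag 1-10
#' autocorrelations and a Shapiro-Wilk statistic are attached. Streams that
#' are constant over the data are flagged as degenerate rather than
#' propagating NaN.
#'
#' @inheritParams viterbi
#' @return list of class `pseudoRes` with per-stream normal residuals
#'   (`stepRes`, `turnRes`, `diveRes`), `acf` (3 x 10), `shapiroW` and
#'   `degenerate` flags.
#' @export
pseudoRes <- function(fit, records) {
  par <- fitPar(fit)
  P <- hmmAllProbs(par, records)
  aInd <- hmmStartIndex(records)
  Tn <- nrow(P); N <- ncol(P)
  ss <- gammaMomentsToShapeScale(par$stepMean, par$stepSd)
  # forecast state weights given observations strictly before t
  W <- matrix(0, Tn, N)
  bounds <- cbind(aInd, c(aInd[-1] - 1, Tn))
  for (b in seq_len(nrow(bounds))) {
    i0 <- bounds[b, 1]; i1 <- bounds[b, 2]
    W[i0, ] <- par$delta
    if (i1 > i0) {
      v <- par$delta * P[i0, ]; v <- v / sum(v)
      for (t in (i0 + 1):i1) {
        W[t, ] <- v %*% par$gamma
        v <- W[t, ] * P[t, ]; v <- v / sum(v)
      }
    }
  }
  # von Mises CDF per state on an interpolation grid
  angGrid <- seq(-pi, pi, length.out = 2048)
  vmCdf <- lapply(seq_len(N), function(k) {
    dens <- dvonmises(angGrid, par$turnMean[k], par$turnKappa[k])
    cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 *
                      diff(angGrid)))
    cdf / cdf[length(cdf)]
  })
  u <- matrix(NA_real_, Tn, 3)
  for (t in seq_len(Tn)) {
    w <- W[t, ]
    if (!is.na(records$step_km[t]))
      u[t, 1] <- sum(w * pgamma(records$step_km[t], shape = ss$shape,
                                scale = ss$scale))
    if (!is.na(records$turn_rad[t]))
      u[t, 2] <- sum(w * vapply(seq_len(N), function(k)
        approx(angGrid, vmCdf[[k]], records$turn_rad[t])$y, numeric(1)))
    if (!is.na(records$n_dives[t])) {
      x <- records$n_dives[t]
      u[t, 3] <- sum(w * (ppois(x - 1, par$diveRate) +
                            0.5 * dpois(x, par$diveRate)))
    }
  }
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  res <- list(stepRes = qnorm(clamp(u[, 1])),
              turnRes = qnorm(clamp(u[, 2])),
              diveRes = qnorm(clamp(u[, 3])))
  streams <- c("step_km", "turn_rad", "n_dives")
  degen <- vapply(streams, function(s) {
    v <- records[[s]][!is.na(records[[s]])]
    length(unique(v)) <= 1
  }, logical(1))
  acfTab <- t(vapply(res, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 12 || sd(r) == 0) return(rep(NA_real_, 10))
    acf(r, lag.max = 10, plot = FALSE)$acf[2:11, 1, 1]
  }, numeric(10)))
  shap <- vapply(res, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 12 || sd(r) == 0) return(NA_real_)
    shapiro.test(r[seq_len(min(length(r), 5000))])$statistic
  }, numeric(1))
  out <- list(stepRes = res$stepRes, turnRes = res$turnRes,
              diveRes = res$diveRes, acf = acfTab, shapiroW = shap,
              degenerate = degen)
  class(out) <- "pseudoRes"
  out
}

#' Rubin's-rules pooling of repeated estimates
#'
#' Pools M imputation-specific parameter estimates: pooled point estimate =
#' mean; total variance = mean within-imputation variance +
#' (1 + 1/M) * between-imputation variance.
#'
#' @param estimates M x p matrix of per-imputation estimates (working scale).
#' @param variances M x p matrix of per-imputation variances (may be NULL or
#'   all-zero when only point pooling is wanted).
#' @return list with `estimate`, `within`, `between`, `total` (length-p).
#' @export
poolRubin <- function(estimates, variances = NULL) {
  estimates <- as.matrix(estimates)
  M <- nrow(estimates)
  if (M < 2) stop("need at least 2 imputations")
  if (is.null(variances)) variances <- matrix(0, M, ncol(estimates))
  variances <- as.matrix(variances)
  stopifnot(all(dim(variances) == dim(estimates)))
  est <- colMeans(estimates)
  within <- colMeans(variances)
  between <- apply(estimates, 2, var)
  list(estimate = est, within = within, between = between,
       total = within + (1 + 1 / M) * between)
}

#' Pool HMM fits across multiple imputations
#'
#' Applies [poolRubin()] to the working-scale parameters of a list of
#' `hmmFit` objects (identical spec, canonical dive-rate state ordering) and
#' back-transforms the pooled point estimates to the natural scale. Fits
#' whose dive-rate ordering is not ascending (label misalignment) cause an
#' error naming them.
#'
#' @param fits list of `hmmFit` objects.
#' @return object of class `hmmFitPooled`: pooled natural parameters plus the
#'   `pooled` working-scale summary from [poolRubin()] and `M`.
#' @export
poolFits <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "hmmFit")))
  N <- fits[[1]]$nStates
  if (!all(vapply(fits, function(f) f$nStates, numeric(1)) == N))
    stop("fits have differing numbers of states")
  mis <- which(vapply(fits, function(f) is.unsorted(f$diveRate), TRUE))
  if (length(mis))
    stop("state labels misaligned (dive rates not ascending) in fit(s): ",
         paste(mis, collapse = ", "))
  W <- t(vapply(fits, function(f) f$wpar, numeric(hmmNpar(N))))
  V <- if (all(vapply(fits, function(f) !is.null(f$wvar), TRUE)))
    t(vapply(fits, function(f) f$wvar, numeric(hmmNpar(N)))) else NULL
  pooled <- poolRubin(W, V)
  par <- hmmUnpack(pooled$estimate, N)
  ss <- gammaMomentsToShapeScale(par$stepMean, par$stepSd)
  out <- c(par, list(stepShape = ss$shape, stepScale = ss$scale,
                     pooled = pooled, M = length(fits), nStates = N,
                     stateNames = fits[[1]]$stateNames))
  class(out) <- c("hmmFitPooled", "hmmFit")
  out
}

#' Fit the HMM to multiple imputations of the position process
#'
#' Practical multiple-imputation fitting: a pilot fit with full multi-start
#' on the first imputation's records, then each imputation refit from the
#' pilot's estimates (single start), pooled by Rubin's rules.
#'
#' @param recordsList list of per-imputation record data.frames (identical
#'   shape).
#' @param nStates,nStarts,seed,hessian passed to [fitHMM()].
#' @return list with `fits` (per-imputation `hmmFit`s), `pilot`, and
#'   `pooled` (an `hmmFitPooled`).
#' @export
mifitHMM <- function(recordsList, nStates = 3, nStarts = 25, seed = NULL,
                     hessian = FALSE) {
  stopifnot(is.list(recordsList), length(recordsList) >= 2)
  pilot <- fitHMM(recordsList[[1]], nStates = nStates, nStarts = nStarts,
                  seed = seed)
  init <- fitPar(pilot)
  fits <- lapply(recordsList, function(r)
    fitHMM(r, nStates = nStates, initPar = init, hessian = hessian))
  list(fits = fits, pilot = pilot, pooled = poolFits(fits))
}
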