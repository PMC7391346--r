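#' Multinomial logistic regression of behavioral state on a covariate
#'
#' Softmax regression of the decoded state (baseline = state 1, transit) on a
#' single covariate (here the interval's median water temperature), fitted by
#' Newton-Raphson on the multinomial log-likelihood; convergence when the
#' gradient infinity-norm falls below 1e-8. Complete or quasi-complete
#' separation makes the MLE diverge; with `ridge > 0` a quadratic penalty
#' stabilizes the fit, otherwise an error suggests it.
#'
#' @param states integer vector of decoded states in 1..K.
#' @param x covariate vector (same length; rows with NA in either are
#'   dropped).
#' @param ridge penalty weight on the squared coefficients (default 0; the
#'   suggested fallback is 1e-6).
#' @param maxit Newton iteration cap.
#' @return object of class `multinomFit`: `coef` ((K-1) x 2 matrix of
#'   intercept and slope per non-baseline state), `se`, `z`, `p` (Wald),
#'   `loglik`, `fitted` function mapping covariate values to a K-column
#'   probability matrix, `levels`, `n`.
#' @export
fitMultinomial <- function(states, x, ridge = 0, maxit = 200) {
  ok <- !is.na(states) & !is.na(x)
  states <- as.integer(states[ok]); x <- as.numeric(x[ok])
  K <- max(states)
  if (K < 2) stop("need at least 2 state categories")
  cnt <- tabulate(states, K)
  if (any(cnt < 10)) stop("fewer than 10 observations in state(s): ",
                          paste(which(cnt < 10), collapse = ", "))
  n <- length(states)
  X <- cbind(1, x)
  Y <- matrix(0, n, K - 1)
  for (k in 2:K) Y[states == k, k - 1] <- 1
  B <- matrix(0, 2, K - 1)     # columns: states 2..K; rows: intercept, slope
  p <- 2 * (K - 1)
  for (it in seq_len(maxit)) {
    eta <- X %*% B
    denom <- 1 + rowSums(exp(eta))
    P <- exp(eta) / denom      # n x (K-1)
    grad <- as.vector(t(X) %*% (Y - P)) - 2 * ridge * as.vector(B)
    H <- matrix(0, p, p)
    for (a in seq_len(K - 1)) for (b in seq_len(K - 1)) {
      w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      H[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)] <- t(X) %*% (X * w)
    }
    H <- H + diag(2 * ridge, p)
    if (max(abs(grad)) < 1e-8) break
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      stop("Newton step failed (possible complete separation); ",
           "retry with ridge = 1e-6")
    B <- B + matrix(step, 2, K - 1)
    if (max(abs(B)) > 1e3)
      stop("coefficients diverging (complete separation); ",
           "retry with ridge = 1e-6")
  }
  if (max(abs(grad)) >= 1e-8)
    warning("Newton-Raphson did not reach the 1e-8 gradient tolerance in ",
            maxit, " iterations")
  V <- solve(H)
  se <- matrix(sqrt(diag(V)), 2, K - 1)
  # (quasi-)complete separation: the MLE sits at a degenerate optimum with
  # meaningless curvature; standard errors blow up while the gradient vanishes
  if (ridge == 0 && max(se) > 100)
    stop("standard errors diverging (complete separation); ",
         "retry with ridge = 1e-6")
  eta <- X %*% B
  ll <- sum(log(cbind(1, exp(eta)) / (1 + rowSums(exp(eta))))[
    cbind(seq_len(n), states)])
  coef <- t(B); rownames(coef) <- paste0("state", 2:K)
  colnames(coef) <- c("intercept", "slope")
  seT <- t(se); dimnames(seT) <- dimnames(coef)
  fitted <- function(xnew) {
    e <- cbind(1, as.numeric(xnew)) %*% B
    pr <- cbind(1, exp(e)) / (1 + rowSums(exp(e)))
    colnames(pr) <- paste0("state", 1:K)
    pr
  }
  out <- list(coef = coef, se = seT, z = coef / seT,
              p = 2 * pnorm(-abs(coef / seT)),
              loglik = ll, fitted = fitted, levels = seq_len(K), n = n,
              ridge = ridge)
  class(out) <- "multinomFit"
  out
}

#' @export
print.multinomFit <- function(x, ...) {
  cat("multinomFit (baseline = state 1):", x$n, "observations, logLik",
      format(x$loglik, digits = 8), "\n")
  tab <- data.frame(coef = as.vector(x$coef), se = as.vector(x$se),
                    z = as.vector(x$z), p = as.vector(x$p))
  rownames(tab) <- paste(rep(rownames(x$coef), 2),
                         rep(colnames(x$coef), each = nrow(x$coef)))
  print(tab)
  invisible(x)
}

#' Great-circle distance to the coastline
#'
#' The coastline is the zero-elevation crossing of the bathymetry: all cells
#' whose elevation sign differs from a 4-neighbour. Each point's distance is
#' the great-circle distance (km) to the nearest such cell centre; points on
#' land (positive elevation at the point) are flagged.
#'
#' @param lon,lat query coordinates.
#' @param grid a `bathymetryGrid`.
#' @return data.frame with `dist_km` and logical `on_land`.
#' @export
distanceToCoast <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "bathymetryGrid"))
  z <- grid$z
  sea <- z < 0
  if (all(sea, na.rm = TRUE) || all(!sea, na.rm = TRUE))
    stop("grid is all sea or all land: no coastline")
  nx <- nrow(z); ny <- ncol(z)
  s <- ifelse(is.na(z), NA, sea)
  nb <- function(m, dx, dy) {
    out <- matrix(NA, nx, ny)
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    out[okx, oky] <- m[xs[okx], ys[oky]]
    out
  }
  coast <- matrix(FALSE, nx, ny)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nbs <- nb(s, d[1], d[2])
    coast <- coast | (!is.na(s) & !is.na(nbs) & s != nbs)
  }
  idx <- which(coast, arr.ind = TRUE)
  cc <- cbind(grid$lon[idx[, 1]], grid$lat[idx[, 2]])
  dist <- vapply(seq_along(lon), function(i)
    min(geosphere::distGeo(c(lon[i], lat[i]), cc)) / 1000, numeric(1))
  elev <- bathyValue(grid, lon, lat)
  data.frame(dist_km = dist, on_land = !is.na(elev) & elev > 0)
}

#' Activity budget over a binned covariate
#'
#' Counts decoded states in closed-left half-open covariate bins [a, a + w)
#' and reports within-bin state proportions. Used for activity versus
#' distance-to-coast (default width 10 km) and versus seafloor depth
#' (default width 400 m).
#'
#' @param states integer decoded states (1..K).
#' @param covariate numeric covariate aligned with `states`.
#' @param width positive bin width.
#' @param origin left edge of the bin lattice (default 0 for nonnegative
#'   covariates, otherwise floor(min/width) * width).
#' @return data.frame of class `activityBudget`: `bin_lo`, `bin_hi`, `count`,
#'   and one proportion column per state.
#' @export
activityBudget <- function(states, covariate, width, origin = NULL) {
  if (width <= 0) stop("bin width must be positive")
  ok <- !is.na(states) & !is.na(covariate)
  states <- as.integer(states[ok]); covariate <- covariate[ok]
  K <- max(states)
  if (is.null(origin))
    origin <- if (min(covariate) >= 0) 0 else floor(min(covariate) / width) * width
  b <- floor((covariate - origin) / width)
  bins <- seq(min(b), max(b))
  out <- data.frame(bin_lo = origin + bins * width,
                    bin_hi = origin + (bins + 1) * width,
                    count = 0L)
  pr <- matrix(NA_real_, length(bins), K,
               dimnames = list(NULL, paste0("p_state", 1:K)))
  for (j in seq_along(bins)) {
    sel <- b == bins[j]
    out$count[j] <- sum(sel)
    if (any(sel)) pr[j, ] <- tabulate(states[sel], K) / sum(sel)
  }
  out <- cbind(out, pr)
  class(out) <- c("activityBudget", "data.frame")
  out
}
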