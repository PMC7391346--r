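#' Gamma moment bridge
#'
#' The HMM reports state-dependent step-length distributions as mean and SD
#' (km); the Gamma density is parameterized by shape and scale. These two
#' helpers convert between the parameterizations exactly:
#' shape = mean^2/sd^2, scale = sd^2/mean.
#'
#' @param mean,sd positive numerics (vectorized).
#' @return `gammaMomentsToShapeScale`: list with `shape`, `scale`.
#' @export
gammaMomentsToShapeScale <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) stop("mean and sd must be positive")
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' @rdname gammaMomentsToShapeScale
#' @param shape,scale positive numerics.
#' @export
gammaShapeScaleToMoments <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be positive")
  list(mean = shape * scale, sd = sqrt(shape) * scale)
}

#' von Mises distribution
#'
#' Density, random generation, CDF and the circular-SD/concentration bridge
#' for the von Mises distribution on (-pi, pi], used for turning angles.
#' `vonMisesSdToKappa` inverts the mean resultant length relation
#' A(kappa) = I1(kappa)/I0(kappa) = exp(-s^2/2) so that generator inputs can
#' be stated as an angular mean and circular SD `s` (radians).
#'
#' @param x angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @export
dvonmises <- function(x, mu, kappa) {
  exp(kappa * (cos(x - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname dvonmises
#' @param n number of draws.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(wrapAngle(runif(n, -pi, pi) + mu))
  # Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrapAngle(out + mu)
}

#' @rdname dvonmises
#' @param q upper angle (radians in (-pi, pi]).
#' @export
pvonmises <- function(q, mu, kappa) {
  vapply(q, function(qi)
    integrate(dvonmises, -pi, qi, mu = mu, kappa = kappa,
              rel.tol = 1e-9)$value, numeric(1))
}

#' @rdname dvonmises
#' @param s circular standard deviation (radians, > 0).
#' @export
vonMisesSdToKappa <- function(s) {
  vapply(s, function(si) {
    stopifnot(si > 0)
    R <- exp(-si^2 / 2)
    A <- function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - R
    uniroot(A, c(1e-10, 1e4), tol = 1e-12)$root
  }, numeric(1))
}

#' @rdname dvonmises
#' @export
vonMisesKappaToSd <- function(kappa) {
  R <- besselI(kappa, 1, TRUE) / besselI(kappa, 0, TRUE)
  sqrt(-2 * log(R))
}

#' Wrap angles to (-pi, pi]
#' @param a angles in radians.
#' @export
wrapAngle <- function(a) {
  w <- -((-a + pi) %% (2 * pi) - pi)
  w
}
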