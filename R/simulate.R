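#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data module. The
#' defaults are the fitted values reported for the nine-turtle Tyrrhenian
#' study: a 3-state switching model (transit, low-intensity diving,
#' high-intensity diving) observed at 6-hr intervals with Gamma step lengths
#' (means 8.152/6.2/5.3 km, SDs 3.27/2.0/1.5), von Mises turning angles
#' (means 0.01/0.08/-0.11 rad with circular SDs 1.4/1.85/1.91 converted to
#' concentrations), Poisson dive counts (rates 1.6/6.54/14.12 per 6 h), the
#' published transition matrix (diagonal 0.86/0.80/0.86), and Argos error
#' ellipses whose semi-major axis is log-normal with median 4,637 m and mean
#' 14,198 m, minor/major axis ratio 802/14198, and a wrapped-normal
#' orientation (87.64 deg, SD 30.41) measured from the x-axis (east).
#'
#' @param n_animals number of simulated animals.
#' @param n_intervals regular 6-hr intervals per animal.
#' @param interval_h interval length, hours.
#' @param step_mean,step_sd per-state Gamma step mean/SD (km).
#' @param turn_mean,turn_sd per-state von Mises mean and circular SD (rad).
#' @param dive_rate per-state Poisson dive rate (per interval).
#' @param gamma 3x3 row-stochastic transition matrix.
#' @param delta initial state distribution; default the stationary
#'   distribution of `gamma`.
#' @param ellipse_major_median,ellipse_major_mean log-normal semi-major axis
#'   median and mean (m); mean 0 disables location error entirely.
#' @param ellipse_axis_ratio semi-minor / semi-major ratio.
#' @param ellipse_orient_mean,ellipse_orient_sd orientation (deg from east)
#'   normal parameters, wrapped to [0, 180).
#' @param fixes_per_interval Poisson mean number of Argos fixes per interval.
#' @param temp_base,temp_seasonal_amp,temp_lapse,temp_noise_sd water
#'   temperature field: surface base (C), seasonal amplitude (C), vertical
#'   lapse (C per m depth), measurement noise SD (C).
#' @param depth_scale per-state Gamma scale of dive maximum depth beyond the
#'   4-m dive threshold (m).
#' @param haulout_prob probability of a haul-out in a transit interval.
#' @param t0 track start (seconds since epoch or ISO string).
#' @param centre study centroid `c(lon, lat)`.
#' @param bathy_halfwidth_deg,bathy_cellsize_deg,bathy_peak_m,
#'   bathy_slope_m_per_km,bathy_floor_m island bathymetry fixture geometry.
#' @param seed integer RNG seed.
#' @return list of class `simConfig`.
#' @export
simConfig <- function(n_animals = 9,
                      n_intervals = 600,
                      interval_h = 6,
                      step_mean = c(8.152, 6.2, 5.3),
                      step_sd = c(3.27, 2.0, 1.5),
                      turn_mean = c(0.01, 0.08, -0.11),
                      turn_sd = c(1.4, 1.85, 1.91),
                      dive_rate = c(1.6, 6.54, 14.12),
                      gamma = matrix(c(0.86, 0.13, 0.01,
                                       0.13, 0.80, 0.07,
                                       0.01, 0.13, 0.86),
                                     3, 3, byrow = TRUE),
                      delta = NULL,
                      ellipse_major_median = 4637,
                      ellipse_major_mean = 14198,
                      ellipse_axis_ratio = 802 / 14198,
                      ellipse_orient_mean = 87.64,
                      ellipse_orient_sd = 30.41,
                      fixes_per_interval = 3,
                      temp_base = 19,
                      temp_seasonal_amp = 4,
                      temp_lapse = 0.05,
                      temp_noise_sd = 0.3,
                      depth_scale = c(15, 40, 60),
                      haulout_prob = 0.3,
                      t0 = "2017-06-09T00:00:00",
                      centre = studyCentre(),
                      bathy_halfwidth_deg = 8,
                      bathy_cellsize_deg = 0.05,
                      bathy_peak_m = 1000,
                      bathy_slope_m_per_km = 8,
                      bathy_floor_m = -3600,
                      seed = 1L) {
  N <- length(step_mean)
  stopifnot(nrow(gamma) == N, ncol(gamma) == N)
  if (any(gamma < 0) || any(abs(rowSums(gamma) - 1) > 1e-12))
    stop("gamma must be row-stochastic")
  if (is.null(delta)) delta <- stationaryDistribution(gamma)
  if (abs(sum(delta) - 1) > 1e-12) stop("delta must sum to 1")
  if (any(step_mean <= 0) || any(step_sd <= 0) || any(dive_rate <= 0))
    stop("emission rates and moments must be positive")
  cfg <- list(
    n_animals = n_animals, n_intervals = n_intervals, interval_h = interval_h,
    step_mean = step_mean, step_sd = step_sd,
    turn_mean = turn_mean, turn_sd = turn_sd,
    turn_kappa = vonMisesSdToKappa(turn_sd),
    dive_rate = dive_rate, gamma = gamma, delta = delta,
    ellipse_major_median = ellipse_major_median,
    ellipse_major_mean = ellipse_major_mean,
    ellipse_axis_ratio = ellipse_axis_ratio,
    ellipse_orient_mean = ellipse_orient_mean,
    ellipse_orient_sd = ellipse_orient_sd,
    fixes_per_interval = fixes_per_interval,
    temp_base = temp_base, temp_seasonal_amp = temp_seasonal_amp,
    temp_lapse = temp_lapse, temp_noise_sd = temp_noise_sd,
    depth_scale = depth_scale, haulout_prob = haulout_prob,
    t0 = parseTime(t0), centre = centre,
    bathy_halfwidth_deg = bathy_halfwidth_deg,
    bathy_cellsize_deg = bathy_cellsize_deg,
    bathy_peak_m = bathy_peak_m,
    bathy_slope_m_per_km = bathy_slope_m_per_km,
    bathy_floor_m = bathy_floor_m,
    seed = as.integer(seed))
  class(cfg) <- "simConfig"
  cfg
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `gamma` for eigenvalue 1, normalized to sum to 1.
#' @param gamma row-stochastic matrix.
#' @export
stationaryDistribution <- function(gamma) {
  e <- eigen(t(gamma))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Simulate one animal's state chain, track and interval observations
#'
#' States follow the Markov chain (`delta`, `gamma`); conditional on state,
#' the interval's step length is Gamma, turning angle von Mises and dive
#' count Poisson. Positions are built by dead reckoning in the local planar
#' frame (heading accumulates the turning angles from a uniform initial
#' heading) and inverse-projected to lon/lat. Uses the current RNG stream;
#' seed with [set.seed()] or via [simulateDataset()].
#'
#' @param config a [simConfig()].
#' @param animal_id identifier string.
#' @return list with `states` (length `n_intervals`), `times` (grid of
#'   `n_intervals + 1` instants, s), `positions` (matrix `(n+1) x 2` of km in
#'   the planar frame), `lonlat`, and `obs` (data.frame: `animal_id`,
#'   `interval_start`, `step_km`, `turn_rad`, `n_dives`).
#' @export
simulateHMMTrack <- function(config, animal_id = "A1") {
  stopifnot(inherits(config, "simConfig"))
  N <- length(config$step_mean)
  Tn <- config$n_intervals
  if (Tn < 1) stop("n_intervals must be >= 1")
  states <- integer(Tn)
  states[1] <- sample.int(N, 1, prob = config$delta)
  for (t in seq_len(Tn - 1))
    states[t + 1] <- sample.int(N, 1, prob = config$gamma[states[t], ])
  ss <- gammaMomentsToShapeScale(config$step_mean, config$step_sd)
  steps <- rgamma(Tn, shape = ss$shape[states], scale = ss$scale[states])
  turns <- numeric(Tn)
  for (k in seq_len(N)) {
    idx <- which(states == k)
    if (length(idx))
      turns[idx] <- rvonmises(length(idx), config$turn_mean[k],
                              config$turn_kappa[k])
  }
  ndives <- rpois(Tn, config$dive_rate[states])
  heading <- runif(1, -pi, pi) + cumsum(turns)
  # start positions scattered around the release area (~10 km)
  pos <- matrix(0, Tn + 1, 2)
  pos[1, ] <- rnorm(2, 0, 10)
  pos[-1, ] <- pos[rep(1, Tn), , drop = FALSE] +
    cbind(cumsum(steps * sin(heading)), cumsum(steps * cos(heading)))
  times <- config$t0 + 3600 * config$interval_h * (0:Tn)
  obs <- data.frame(
    animal_id = animal_id,
    interval_start = times[seq_len(Tn)],
    step_km = steps, turn_rad = turns, n_dives = ndives,
    stringsAsFactors = FALSE)
  list(states = states, times = times, positions = pos,
       lonlat = kmToLonlat(pos[, 1], pos[, 2], config$centre), obs = obs)
}

#' Corrupt a true track with Argos-style sampling and location error
#'
#' Fix times are irregular: a Poisson number of fixes per interval at uniform
#' times (plus one fix pinned at the track start so downstream grids anchor
#' at release). The true position at a fix time is linearly interpolated
#' between grid positions; each fix is displaced by a bivariate normal draw
#' whose covariance derives from a sampled error ellipse via
#' [ellipseToCov()]. Setting `ellipse_major_mean = 0` in the config yields
#' error-free fixes with zero-size ellipses.
#'
#' @param track output of [simulateHMMTrack()].
#' @param config a [simConfig()].
#' @param animal_id identifier string.
#' @return `argosFixes` data.frame (see [readArgos()]).
#' @export
applyArgosError <- function(track, config, animal_id = "A1") {
  times <- track$times
  Tn <- length(times) - 1
  nf <- rpois(Tn, config$fixes_per_interval)
  ft <- sort(c(times[1], unlist(lapply(seq_len(Tn), function(i)
    runif(nf[i], times[i], times[i + 1])))))
  # true planar position by linear interpolation on the grid
  px <- approx(times, track$positions[, 1], xout = ft)$y
  py <- approx(times, track$positions[, 2], xout = ft)$y
  n <- length(ft)
  if (config$ellipse_major_mean <= 0) {
    maj <- rep(0, n)
  } else {
    sdlog <- sqrt(2 * log(config$ellipse_major_mean /
                            config$ellipse_major_median))
    maj <- rlnorm(n, meanlog = log(config$ellipse_major_median),
                  sdlog = sdlog)
  }
  mnr <- maj * config$ellipse_axis_ratio
  ori <- rnorm(n, config$ellipse_orient_mean, config$ellipse_orient_sd) %% 180
  for (i in seq_len(n)) {
    if (maj[i] <= 0) next
    S <- ellipseToCov(maj[i], mnr[i], ori[i]) / 1e6   # m^2 -> km^2
    L <- t(chol(S + diag(1e-12, 2)))
    e <- L %*% rnorm(2)
    px[i] <- px[i] + e[1]; py[i] <- py[i] + e[2]
  }
  ll <- kmToLonlat(px, py, config$centre)
  out <- data.frame(
    animal_id = animal_id, time = ft, lon = ll[, 1], lat = ll[, 2],
    semi_major_m = maj, semi_minor_m = mnr, orientation_deg = ori,
    stringsAsFactors = FALSE)
  class(out) <- c("argosFixes", "data.frame")
  out
}

#' Simulate dive records, temperature profiles and haul-outs
#'
#' Places the per-interval dive counts uniformly within their interval. Each
#' dive gets a maximum depth of 4 m plus a state-dependent Gamma excess and a
#' 17-cut-point temperature profile (depths equally spaced from the 4-m dive
#' threshold to the maximum depth) from the configured temperature field:
#' base + seasonal sine - lapse * depth + noise, clamped to the sensor range
#' [-5, 35] C. Haul-outs (>= 5 min) occur only in transit intervals — a
#' fixture-richness assumption, not an inference.
#'
#' @inheritParams applyArgosError
#' @return list with `dives`, `profiles`, `haulouts` data.frames.
#' @export
simulateDivesTemps <- function(track, config, animal_id = "A1") {
  times <- track$times
  Tn <- length(track$states)
  dives <- list(); profs <- list(); hauls <- list()
  yearS <- 365.25 * 86400
  for (i in seq_len(Tn)) {
    st <- track$states[i]
    nd <- track$obs$n_dives[i]
    if (nd > 0) {
      t0 <- sort(runif(nd, times[i], times[i + 1] - 60))
      dur <- pmin(runif(nd, 120, 1800), times[i + 1] - t0)
      maxd <- 4 + rgamma(nd, shape = 2, scale = config$depth_scale[st] / 2)
      dives[[length(dives) + 1]] <- data.frame(
        animal_id = animal_id, start = t0, end = t0 + dur,
        max_depth_m = maxd, duration_s = dur, stringsAsFactors = FALSE)
      for (j in seq_len(nd)) {
        dep <- seq(4, maxd[j], length.out = 17)
        seas <- config$temp_seasonal_amp * sin(2 * pi * t0[j] / yearS)
        tmp <- config$temp_base + seas - config$temp_lapse * dep +
          rnorm(17, 0, config$temp_noise_sd)
        profs[[length(profs) + 1]] <- data.frame(
          animal_id = animal_id, dive_start = t0[j], index = 1:17,
          depth_m = dep, temp_C = pmin(pmax(tmp, -5), 35),
          stringsAsFactors = FALSE)
      }
    }
    if (st == 1 && runif(1) < config$haulout_prob) {
      h0 <- runif(1, times[i], times[i + 1] - 3600)
      hauls[[length(hauls) + 1]] <- data.frame(
        animal_id = animal_id, start = h0,
        end = h0 + runif(1, 300, 3600), stringsAsFactors = FALSE)
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(
    dives = bind(dives, data.frame(animal_id = character(), start = numeric(),
                                   end = numeric(), max_depth_m = numeric(),
                                   duration_s = numeric())),
    profiles = bind(profs, data.frame(animal_id = character(),
                                      dive_start = numeric(), index = integer(),
                                      depth_m = numeric(), temp_C = numeric())),
    haulouts = bind(hauls, data.frame(animal_id = character(),
                                      start = numeric(), end = numeric())))
}

#' Radially symmetric island bathymetry fixture
#'
#' Elevation = peak - slope * (great-circle distance from the study centroid,
#' km), clipped below at the abyssal floor. The coastline (zero crossing) is
#' therefore a circle of radius peak/slope km around the centroid.
#'
#' @param config a [simConfig()].
#' @return a `bathymetryGrid` (see [readBathymetry()]).
#' @export
makeBathymetryIsland <- function(config) {
  cs <- config$bathy_cellsize_deg
  hw <- config$bathy_halfwidth_deg
  lon <- seq(config$centre[1] - hw + cs / 2, config$centre[1] + hw, by = cs)
  lat <- seq(config$centre[2] - hw + cs / 2, config$centre[2] + hw, by = cs)
  g <- expand.grid(lon = lon, lat = lat)
  d <- geosphere::distGeo(config$centre, as.matrix(g)) / 1000
  z <- pmax(config$bathy_peak_m - config$bathy_slope_m_per_km * d,
            config$bathy_floor_m)
  grid <- list(lon = lon, lat = lat,
               z = matrix(z, length(lon), length(lat)), cellsize = cs)
  class(grid) <- "bathymetryGrid"
  grid
}

#' Generate a complete synthetic tagged-animal dataset
#'
#' Drives all generator stages under a single seed: per animal a state chain
#' and true track, Argos-corrupted fixes, dives with temperature profiles and
#' haul-outs, plus the island bathymetry. Regeneration from the same config
#' (which includes the seed) is bit-identical.
#'
#' @param config a [simConfig()].
#' @return list of class `simulatedDataset` with elements `config`, `truth`
#'   (per-interval state/step/turn/dive table with animal ids), `tracks`
#'   (list of true tracks), `argos`, `dives`, `profiles`, `haulouts`,
#'   `bathymetry`.
#' @export
simulateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  ids <- sprintf("SIM%02d", seq_len(config$n_animals))
  tracks <- list(); argos <- list(); dv <- list(); pf <- list(); ho <- list()
  truth <- list()
  for (a in seq_along(ids)) {
    tr <- simulateHMMTrack(config, ids[a])
    tracks[[ids[a]]] <- tr
    argos[[a]] <- applyArgosError(tr, config, ids[a])
    aux <- simulateDivesTemps(tr, config, ids[a])
    dv[[a]] <- aux$dives; pf[[a]] <- aux$profiles; ho[[a]] <- aux$haulouts
    truth[[a]] <- cbind(tr$obs, state = tr$states)
  }
  argos <- do.call(rbind, argos)
  class(argos) <- c("argosFixes", "data.frame")
  out <- list(config = config,
              truth = do.call(rbind, truth),
              tracks = tracks,
              argos = argos,
              dives = do.call(rbind, dv),
              profiles = do.call(rbind, pf),
              haulouts = do.call(rbind, ho),
              bathymetry = makeBathymetryIsland(config))
  class(out) <- "simulatedDataset"
  out
}

#' @export
print.simulatedDataset <- function(x, ...) {
  cat("simulatedDataset:", x$config$n_animals, "animals x",
      x$config$n_intervals, "intervals of", x$config$interval_h, "h\n")
  cat("  ", nrow(x$argos), "Argos fixes,", nrow(x$dives), "dives,",
      nrow(x$profiles) / 17, "temperature profiles,",
      nrow(x$haulouts), "haul-outs\n")
  invisible(x)
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits `argos.csv`, `dives.csv`, `profiles.csv`, `haulouts.csv`,
#' `bathymetry.asc` and the ground-truth table `truth.csv`.
#'
#' @param dataset a `simulatedDataset`.
#' @param dir output directory (created if needed).
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeArgos(dataset$argos, file.path(dir, "argos.csv"))
  writeDives(dataset$dives, file.path(dir, "dives.csv"))
  writeProfiles(dataset$profiles, file.path(dir, "profiles.csv"))
  writeHaulouts(dataset$haulouts, file.path(dir, "haulouts.csv"))
  writeBathymetry(dataset$bathymetry, file.path(dir, "bathymetry.asc"))
  tr <- dataset$truth
  tr$interval_start <- formatTime(tr$interval_start)
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
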