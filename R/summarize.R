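#' Step lengths and turning angles of a regular track
#'
#' Step i is the great-circle distance (km) between grid positions i and
#' i + 1; the turning angle at step i is the signed difference between the
#' bearings of steps i and i - 1, wrapped to (-pi, pi]. The first interval's
#' turning angle is undefined (NA).
#'
#' @param track a `regularTrack` (or any data.frame with `lon`, `lat` ordered
#'   in time).
#' @return data.frame with one row per interval: `step_km`, `turn_rad`.
#' @export
stepsAndAngles <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("need at least 2 positions")
  p <- cbind(track$lon, track$lat)
  step <- geosphere::distGeo(p[-n, , drop = FALSE],
                             p[-1, , drop = FALSE]) / 1000
  brg <- geosphere::bearing(p[-n, , drop = FALSE],
                            p[-1, , drop = FALSE]) * pi / 180
  turn <- c(NA_real_, wrapAngle(diff(brg)))
  # zero-length steps have no bearing: their turn (and the next) is undefined
  zero <- which(step < 1e-9)
  if (length(zero)) {
    turn[zero] <- NA
    turn[zero + 1] <- NA
  }
  data.frame(step_km = step, turn_rad = turn[seq_len(n - 1)])
}

#' Summary statistics of a temperature profile
#'
#' Unweighted mean, median and SD over the 17 temperature cut points.
#'
#' @param profile data.frame with a `temp_C` column (one dive's 17 rows).
#' @return named numeric vector `c(mean, median, sd)`.
#' @export
summarizeProfile <- function(profile) {
  v <- profile$temp_C
  if (length(v) != 17) stop("profile must have exactly 17 cut points")
  c(mean = mean(v), median = median(v), sd = sd(v))
}

#' Build per-interval observation records
#'
#' Aligns dive, temperature and haul-out data to the regular grid of a track.
#' A dive belongs to the interval containing its start; `n_dives` is the
#' count, `max_depth_m` the maximum, `dive_time_s` the summed duration.
#' Haul-out seconds are the overlap of haul-out spans with the interval
#' (spans crossing a boundary are split proportionally). Temperature follows
#' the two-stage summary: each dive's profile is reduced to (mean, median,
#' SD), then per interval the median of per-dive medians, mean of per-dive
#' means and mean of per-dive SDs are taken; intervals without a temperature
#' dive have missing temperature fields. Dives outside the track span are
#' dropped with a warning.
#'
#' @param track a `regularTrack` for one animal.
#' @param dives,profiles,haulouts data.frames as from [readDives()] etc.
#'   (rows for this animal are selected by `animal_id`).
#' @param diveCoverage optional data.frame (`start`, `end`, seconds) of spans
#'   over which the dive stream was recording; intervals wholly outside
#'   coverage get `n_dives = NA` (missing is distinguished from zero). By
#'   default all intervals are covered.
#' @return data.frame of class `intervalRecords`, one row per grid interval:
#'   `animal_id`, `interval_start`, `step_km`, `turn_rad`, `n_dives`,
#'   `max_depth_m`, `dive_time_s`, `haulout_s`, `temp_median_C`,
#'   `temp_mean_C`, `temp_sd_C`.
#' @export
binIntervals <- function(track, dives = NULL, profiles = NULL,
                         haulouts = NULL, diveCoverage = NULL) {
  id <- track$animal_id[1]
  tt <- track$time
  nI <- length(tt) - 1
  sa <- stepsAndAngles(track)
  rec <- data.frame(
    animal_id = id, interval_start = tt[seq_len(nI)],
    step_km = sa$step_km, turn_rad = sa$turn_rad,
    n_dives = 0L, max_depth_m = NA_real_, dive_time_s = 0,
    haulout_s = 0, temp_median_C = NA_real_, temp_mean_C = NA_real_,
    temp_sd_C = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(dives) && nrow(dives)) {
    dv <- dives[dives$animal_id == id, , drop = FALSE]
    iv <- findInterval(dv$start, tt)
    out <- iv < 1 | iv > nI
    if (any(out)) {
      warning(sum(out), " dive(s) outside the track span dropped")
      dv <- dv[!out, , drop = FALSE]; iv <- iv[!out]
    }
    if (nrow(dv)) {
      cnt <- tapply(rep(1L, nrow(dv)), iv, sum)
      rec$n_dives[as.integer(names(cnt))] <- as.integer(cnt)
      mx <- tapply(dv$max_depth_m, iv, max)
      rec$max_depth_m[as.integer(names(mx))] <- as.numeric(mx)
      du <- tapply(dv$duration_s, iv, sum)
      rec$dive_time_s[as.integer(names(du))] <- as.numeric(du)
    }
  }
  if (!is.null(profiles) && nrow(profiles)) {
    pf <- profiles[profiles$animal_id == id, , drop = FALSE]
    if (nrow(pf)) {
      per <- do.call(rbind, lapply(split(pf, pf$dive_start), function(p)
        data.frame(dive_start = p$dive_start[1],
                   t(summarizeProfile(p)))))
      iv <- findInterval(per$dive_start, tt)
      keep <- iv >= 1 & iv <= nI
      per <- per[keep, , drop = FALSE]; iv <- iv[keep]
      if (nrow(per)) {
        md <- tapply(per$median, iv, median)
        rec$temp_median_C[as.integer(names(md))] <- as.numeric(md)
        mn <- tapply(per$mean, iv, mean)
        rec$temp_mean_C[as.integer(names(mn))] <- as.numeric(mn)
        sdv <- tapply(per$sd, iv, mean)
        rec$temp_sd_C[as.integer(names(sdv))] <- as.numeric(sdv)
      }
    }
  }
  if (!is.null(haulouts) && nrow(haulouts)) {
    ho <- haulouts[haulouts$animal_id == id, , drop = FALSE]
    for (j in seq_len(nrow(ho))) {
      ov <- pmin(tt[-1], ho$end[j]) - pmax(tt[-length(tt)], ho$start[j])
      rec$haulout_s <- rec$haulout_s + pmax(ov, 0)
    }
  }
  if (!is.null(diveCoverage)) {
    covered <- vapply(seq_len(nI), function(i)
      any(diveCoverage$start < tt[i + 1] & diveCoverage$end > tt[i]),
      logical(1))
    rec$n_dives[!covered] <- NA_integer_
  }
  class(rec) <- c("intervalRecords", "data.frame")
  rec
}

#' Exclude the first hours after release
#'
#' Removes, per animal, all interval records starting less than `hours` after
#' that animal's first record (post-release stress window; default 24 h, i.e.
#' exactly 4 records on a 6-hr grid).
#'
#' @param records interval records (possibly several animals).
#' @param hours exclusion window.
#' @return the filtered records; a warning is raised for animals whose whole
#'   track falls inside the window.
#' @export
excludeInitial <- function(records, hours = 24) {
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$animal_id),
                        function(i) {
    t0 <- min(records$interval_start[i])
    ok <- records$interval_start[i] >= t0 + hours * 3600
    if (!any(ok)) warning("animal ", records$animal_id[i[1]],
                          ": track shorter than the exclusion window")
    i[ok]
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
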