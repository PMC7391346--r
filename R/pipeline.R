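#' Pipeline run configuration
#'
#' Collects the settings of the full analysis. Defaults are the study's
#' stated settings: 6-hr intervals, 100 imputations, a 3-state model with 25
#' optimizer starts, 75% isopleths, ellipse axes as 1-sigma extents, 10-km
#' coast-distance bins and 400-m depth bins.
#'
#' @param interval_h regular grid spacing, hours.
#' @param nSims number of position-process imputations.
#' @param nStates,nStarts HMM size and optimizer starts.
#' @param isoplethLevel home-range isopleth level.
#' @param ellipseScale Argos ellipse 1-sigma scale factor.
#' @param coastBinKm,depthBinM activity-budget bin widths.
#' @param excludeAnimals animal ids dropped before fitting.
#' @param excludeHours post-release exclusion window, hours.
#' @param centre planar frame origin `c(lon, lat)`.
#' @param seed root seed; per-stage seeds are derived by fixed offsets.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(interval_h = 6, nSims = 100, nStates = 3,
                      nStarts = 25, isoplethLevel = 0.75, ellipseScale = 1,
                      coastBinKm = 10, depthBinM = 400,
                      excludeAnimals = character(), excludeHours = 24,
                      centre = studyCentre(), seed = 1L) {
  cfg <- list(interval_h = interval_h, nSims = nSims, nStates = nStates,
              nStarts = nStarts, isoplethLevel = isoplethLevel,
              ellipseScale = ellipseScale, coastBinKm = coastBinKm,
              depthBinM = depthBinM, excludeAnimals = excludeAnimals,
              excludeHours = excludeHours, centre = centre,
              seed = as.integer(seed))
  class(cfg) <- "runConfig"
  cfg
}

#' Run the full movement analysis
#'
#' Executes the stages in order: ingest (CSV/ASC inputs or an in-memory
#' [simulateDataset()] object), CTCRW regularization per animal, 6-hr
#' summarization, multiple-imputation HMM fitting with Rubin pooling, state
#' decoding, temperature and coast/bathymetry covariate analyses, and kernel
#' space use. Every stochastic step is seeded from the root seed by fixed
#' offsets, so identical (inputs, config) reproduce identical outputs. If
#' `outDir` is given, stage outputs are written as CSV/JSON plus a plain-text
#' run report with the parameter tables and all warnings.
#'
#' @param data either a `simulatedDataset` or a named list of file paths
#'   (`argos`, `dives`, `profiles`, `haulouts`, `bathymetry`).
#' @param config a [runConfig()].
#' @param outDir optional output directory.
#' @return list of class `pipelineResult` with `tracks`, `records`,
#'   `pooled`, `pilot`, `decoded`, `temperatureModel` (NULL if too few
#'   temperature records), `coastBudget`, `depthBudget`, `homeRanges`,
#'   `overlap`, `warnings`, `config`.
#' @export
runPipeline <- function(data, config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "runConfig"))
  warns <- character()
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  # -- ingest -----------------------------------------------------------
  if (inherits(data, "simulatedDataset")) {
    argos <- data$argos; dives <- data$dives; profiles <- data$profiles
    haulouts <- data$haulouts; bathy <- data$bathymetry
  } else {
    argos <- wcollect(readArgos(data$argos))
    dives <- wcollect(readDives(data$dives))
    profiles <- wcollect(readProfiles(data$profiles))
    haulouts <- wcollect(readHaulouts(data$haulouts))
    bathy <- readBathymetry(data$bathymetry)
  }
  argos <- argos[!(argos$animal_id %in% config$excludeAnimals), ,
                 drop = FALSE]
  ids <- unique(argos$animal_id)
  if (!length(ids)) stop("stage ingest: no animals left after exclusion")
  # -- regularize -------------------------------------------------------
  tracks <- list(); imps <- list()
  for (a in seq_along(ids)) {
    fx <- argos[argos$animal_id == ids[a], , drop = FALSE]
    params <- tryCatch(
      fitCTCRW(fx, centre = config$centre, scale = config$ellipseScale),
      error = function(e) stop("stage regularize (", ids[a], "): ",
                               conditionMessage(e)))
    tracks[[ids[a]]] <- predictRegular(params, fx, config$interval_h)
    imps[[ids[a]]] <- drawImputations(params, fx, nSims = config$nSims,
                                      seed = config$seed + 1000L + a,
                                      interval_h = config$interval_h)
  }
  # -- summarize --------------------------------------------------------
  mkRecords <- function(posList) {
    recs <- lapply(ids, function(id) {
      tr <- tracks[[id]]
      if (!is.null(posList)) {
        tr$x_km <- posList[[id]]$x; tr$y_km <- posList[[id]]$y
        ll <- kmToLonlat(tr$x_km, tr$y_km, config$centre)
        tr$lon <- ll[, 1]; tr$lat <- ll[, 2]
      }
      binIntervals(tr, dives, profiles, haulouts)
    })
    excludeInitial(do.call(rbind, recs), config$excludeHours)
  }
  records <- wcollect(mkRecords(NULL))          # smoothed-mean records
  impRecords <- lapply(seq_len(config$nSims), function(s) {
    wcollect(mkRecords(setNames(lapply(ids, function(id)
      list(x = imps[[id]]$x[s, ], y = imps[[id]]$y[s, ])), ids)))
  })
  # -- fit + pool -------------------------------------------------------
  mi <- mifitHMM(impRecords, nStates = config$nStates,
                 nStarts = config$nStarts, seed = config$seed + 2000L)
  pooled <- mi$pooled
  # -- decode -----------------------------------------------------------
  decoded <- stateProbs(pooled, records)
  # -- covariates -------------------------------------------------------
  tempModel <- NULL
  okTemp <- !is.na(records$temp_median_C)
  if (sum(okTemp) >= 10 * config$nStates &&
      all(tabulate(decoded$viterbi[okTemp], config$nStates) >= 10)) {
    tempModel <- fitMultinomial(decoded$viterbi[okTemp],
                                records$temp_median_C[okTemp])
  }
  posAll <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[[id]]
    n <- nrow(tr)
    data.frame(animal_id = id, lon = tr$lon[seq_len(n - 1)],
               lat = tr$lat[seq_len(n - 1)],
               x_km = tr$x_km[seq_len(n - 1)],
               y_km = tr$y_km[seq_len(n - 1)],
               interval_start = tr$time[seq_len(n - 1)])
  }))
  idx <- match(paste(records$animal_id, records$interval_start),
               paste(posAll$animal_id, posAll$interval_start))
  posAll <- posAll[idx, , drop = FALSE]   # row-aligned with records/decoded
  coast <- distanceToCoast(posAll$lon, posAll$lat, bathy)
  depth <- -bathyValue(bathy, posAll$lon, posAll$lat)  # positive = depth
  coastBudget <- activityBudget(decoded$viterbi, coast$dist_km,
                                config$coastBinKm)
  depthBudget <- activityBudget(decoded$viterbi[depth >= 0 & !is.na(depth)],
                                depth[depth >= 0 & !is.na(depth)],
                                config$depthBinM)
  # -- space use --------------------------------------------------------
  xr <- range(posAll$x_km); yr <- range(posAll$y_km)
  pad <- 0.15 * max(diff(xr), diff(yr)) + 10
  xg <- seq(xr[1] - pad, xr[2] + pad, length.out = 300)
  yg <- seq(yr[1] - pad, yr[2] + pad, length.out = 300)
  grids <- list(); homeRanges <- list()
  for (id in ids) {
    sel <- posAll$animal_id == id
    if (sum(sel) < 30) next
    grids[[id]] <- kdeDensity(posAll$x_km[sel], posAll$y_km[sel],
                              xgrid = xg, ygrid = yg)
    homeRanges[[id]] <- isopleth(grids[[id]], config$isoplethLevel)
  }
  ovl <- if (length(grids) > 1) overlapMatrix(grids) else NULL
  res <- list(tracks = tracks, records = records, pooled = pooled,
              pilot = mi$pilot, decoded = decoded,
              temperatureModel = tempModel, coastBudget = coastBudget,
              depthBudget = depthBudget, homeRanges = homeRanges,
              overlap = ovl, warnings = warns, config = config)
  class(res) <- "pipelineResult"
  if (!is.null(outDir)) writePipelineReport(res, outDir)
  res
}

#' @export
print.pipelineResult <- function(x, ...) {
  cat("pipelineResult:", length(x$tracks), "animals,", nrow(x$records),
      "intervals\n")
  print(x$pooled)
  invisible(x)
}

#' @export
print.hmmFitPooled <- function(x, ...) {
  cat("hmmFitPooled over", x$M, "imputations (Rubin's rules)\n")
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

#' Write pipeline outputs and a run report
#'
#' Emits per-animal regular tracks and interval records as CSV, the pooled
#' model as JSON, budgets and the overlap matrix as CSV, and `report.txt`
#' with the parameter tables (state-dependent distributions and transition
#' matrix), home-range areas, seeds and collected warnings.
#'
#' @param res a `pipelineResult`.
#' @param outDir output directory (created if needed).
#' @export
writePipelineReport <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  recs <- res$records
  recs$interval_start <- formatTime(recs$interval_start)
  utils::write.csv(recs, file.path(outDir, "interval_records.csv"),
                   row.names = FALSE)
  for (id in names(res$tracks)) {
    tr <- as.data.frame(res$tracks[[id]])
    tr$time <- formatTime(tr$time)
    utils::write.csv(tr, file.path(outDir, paste0("track_", id, ".csv")),
                     row.names = FALSE)
  }
  fitOut <- list(
    stateNames = res$pooled$stateNames,
    stepMean = res$pooled$stepMean, stepSd = res$pooled$stepSd,
    turnMean = res$pooled$turnMean, turnKappa = res$pooled$turnKappa,
    diveRate = res$pooled$diveRate, gamma = res$pooled$gamma,
    delta = res$pooled$delta, M = res$pooled$M,
    pilotLoglik = res$pilot$loglik, pilotAIC = res$pilot$aic,
    ellipseScale = res$config$ellipseScale, seed = res$config$seed)
  jsonlite::write_json(fitOut, file.path(outDir, "pooled_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(res$coastBudget),
                   file.path(outDir, "budget_coast.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$depthBudget),
                   file.path(outDir, "budget_depth.csv"), row.names = FALSE)
  if (!is.null(res$overlap))
    utils::write.csv(as.data.frame(res$overlap),
                     file.path(outDir, "overlap.csv"))
  fmtTab <- function(x) paste(capture.output(print(x)), collapse = "\n")
  gm <- round(res$pooled$gamma, 4)
  dimnames(gm) <- list(res$pooled$stateNames, res$pooled$stateNames)
  areas <- vapply(res$homeRanges, function(h) h$area_km2, numeric(1))
  report <- c(
    "movement analysis run report",
    paste("root seed:", res$config$seed),
    paste("interval:", res$config$interval_h, "h; imputations:",
          res$config$nSims, "; states:", res$config$nStates,
          "; starts:", res$config$nStarts),
    paste("ellipse 1-sigma scale factor:", res$config$ellipseScale,
          "(axes treated as", res$config$ellipseScale, "sigma extents)"),
    "", "state-dependent distributions (pooled):",
    fmtTab(data.frame(state = res$pooled$stateNames,
                      step_mean_km = round(res$pooled$stepMean, 4),
                      step_sd_km = round(res$pooled$stepSd, 4),
                      turn_mean_rad = round(res$pooled$turnMean, 4),
                      turn_kappa = round(res$pooled$turnKappa, 4),
                      dive_rate = round(res$pooled$diveRate, 4))),
    "", "transition probability matrix (pooled):", fmtTab(gm),
    "", paste0(res$config$isoplethLevel * 100, "% isopleth areas (km^2):"),
    fmtTab(round(areas, 1)),
    "", paste("warnings (", length(res$warnings), "):"),
    res$warnings)
  writeLines(report, file.path(outDir, "report.txt"))
  invisible(outDir)
}
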