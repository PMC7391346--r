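#' Read Argos location fixes
#'
#' Reads a CSV of Argos fixes with error-ellipse geometry. Mandatory columns:
#' `animal_id, time, lon, lat, semi_major_m, semi_minor_m, orientation_deg`.
#' Unknown columns are ignored. Rows violating basic invariants
#' (|lat| > 90, |lon| > 180, semi-minor > semi-major, negative axes,
#' orientation outside [0, 180), unparseable time) are skipped with a
#' warning. Within each animal, records are sorted by time and exact
#' duplicate timestamps are collapsed to the first record.
#'
#' @param path CSV file path.
#' @return data.frame of class `argosFixes` with columns as above, `time` in
#'   seconds since epoch, sorted by (animal_id, time).
#' @export
readArgos <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time", "lon", "lat",
            "semi_major_m", "semi_minor_m", "orientation_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$animal_id <- as.character(df$animal_id)
  df$time <- suppressWarnings(parseTime(df$time))
  for (nm in need[-(1:2)]) df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  bad <- is.na(df$time) | is.na(df$lon) | is.na(df$lat) |
    abs(df$lat) > 90 | abs(df$lon) > 180 |
    is.na(df$semi_major_m) | is.na(df$semi_minor_m) |
    df$semi_major_m < 0 | df$semi_minor_m < 0 |
    df$semi_minor_m > df$semi_major_m |
    is.na(df$orientation_deg) | df$orientation_deg < 0 |
    df$orientation_deg >= 180
  if (any(bad)) {
    warning(sum(bad), " invalid Argos row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$animal_id, df$time), , drop = FALSE]
  dup <- duplicated(df[c("animal_id", "time")])
  if (any(dup)) {
    message(sum(dup), " duplicate-timestamp fix(es) dropped (kept first)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("argosFixes", "data.frame")
  df
}

#' @rdname readArgos
#' @param fixes `argosFixes` data.frame.
#' @export
writeArgos <- function(fixes, path) {
  out <- as.data.frame(fixes)
  out$time <- formatTime(out$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dive records, temperature profiles and haul-outs
#'
#' Dive CSV columns: `animal_id, start, end, max_depth_m, duration_s`.
#' Dives with `end <= start`, depth < 4 m (the tag's dive definition) or
#' nonpositive duration are rejected with a warning; output is sorted by
#' start within animal.
#'
#' Profile CSV is long format, one row per cut point:
#' `animal_id, dive_start, index, depth_m, temp_C`, `index` in 1..17.
#' Profiles not comprising exactly 17 points, with decreasing depths or with
#' temperatures outside the sensor range [-5, 35] C are rejected with a
#' warning.
#'
#' Haul-out CSV columns: `animal_id, start, end`; spans shorter than 5 min
#' (the tag's haul-out start rule) are rejected.
#'
#' @param path CSV file path.
#' @return `readDives`/`readHaulouts`: data.frames with times in seconds
#'   since epoch. `readProfiles`: data.frame of class `tempProfiles`, long
#'   format, only complete valid profiles retained.
#' @export
readDives <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "start", "end", "max_depth_m", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$animal_id <- as.character(df$animal_id)
  df$start <- parseTime(df$start)
  df$end <- parseTime(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$end <= df$start |
    is.na(df$max_depth_m) | df$max_depth_m < 4 |
    is.na(df$duration_s) | df$duration_s <= 0
  if (any(bad)) {
    warning(sum(bad), " invalid dive record(s) rejected")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$animal_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname readDives
#' @export
readProfiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "dive_start", "index", "depth_m", "temp_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$animal_id <- as.character(df$animal_id)
  df$dive_start <- parseTime(df$dive_start)
  df <- df[order(df$animal_id, df$dive_start, df$index), , drop = FALSE]
  key <- paste(df$animal_id, df$dive_start)
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
    p <- df[i, ]
    ok <- length(i) == 17 && all(p$index == 1:17) &&
      !anyNA(p$depth_m) && !is.unsorted(p$depth_m) &&
      all(p$temp_C >= -5 & p$temp_C <= 35)
    if (ok) i else integer(0)
  }), use.names = FALSE)
  if (length(keep) < nrow(df))
    warning((nrow(df) - length(keep)) / 17, " incomplete/invalid profile(s) rejected")
  df <- df[sort(keep), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tempProfiles", "data.frame")
  df
}

#' @rdname readDives
#' @export
readHaulouts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$animal_id <- as.character(df$animal_id)
  df$start <- parseTime(df$start)
  df$end <- parseTime(df$end)
  bad <- is.na(df$start) | is.na(df$end) | (df$end - df$start) < 300
  if (any(bad)) {
    warning(sum(bad), " invalid haul-out record(s) rejected")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$animal_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname readDives
#' @param dives,profiles,haulouts data.frames as returned by the readers.
#' @export
writeDives <- function(dives, path) {
  out <- as.data.frame(dives)
  out$start <- formatTime(out$start); out$end <- formatTime(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readDives
#' @export
writeProfiles <- function(profiles, path) {
  out <- as.data.frame(profiles)
  out$dive_start <- formatTime(out$dive_start)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readDives
#' @export
writeHaulouts <- function(haulouts, path) {
  out <- as.data.frame(haulouts)
  out$start <- formatTime(out$start); out$end <- formatTime(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bathymetry grids (ESRI ASCII)
#'
#' A `bathymetryGrid` is a regular lon/lat raster of elevation in meters
#' (negative below sea level, positive land) with explicit no-data handling.
#' The on-disk format is the plain-text ESRI ASCII grid (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, then rows from
#' north to south).
#'
#' @param path `.asc` file path.
#' @return `readBathymetry`: a `bathymetryGrid` list with `lon`, `lat`
#'   (ascending cell-centre coordinates), `z` (matrix `[lon, lat]`, `NA` =
#'   no data), `cellsize`.
#' @export
readBathymetry <- function(path) {
  ln <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing georeference header field(s): ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = ln[i:length(ln)], quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr) stop("grid body size does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # row 1 = north
  m[m == nodata] <- NA
  z <- t(m[nr:1, , drop = FALSE])                        # -> z[lon, lat]
  grid <- list(
    lon = hdr$xllcorner + hdr$cellsize * (seq_len(nc) - 0.5),
    lat = hdr$yllcorner + hdr$cellsize * (seq_len(nr) - 0.5),
    z = z, cellsize = hdr$cellsize)
  class(grid) <- "bathymetryGrid"
  grid
}

#' @rdname readBathymetry
#' @param grid a `bathymetryGrid`.
#' @export
writeBathymetry <- function(grid, path) {
  stopifnot(inherits(grid, "bathymetryGrid"))
  nc <- length(grid$lon); nr <- length(grid$lat)
  z <- grid$z
  z[is.na(z)] <- -9999
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(grid$lon[1] - grid$cellsize / 2, digits = 15)),
    paste("yllcorner", format(grid$lat[1] - grid$cellsize / 2, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    "NODATA_value -9999")
  body <- apply(t(z)[nr:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname readBathymetry
#' @param lon,lat query coordinates (vectors of equal length).
#' @return `bathyValue`: elevation (m) at the query points by bilinear
#'   interpolation of the four surrounding cell centres; `NA` outside the
#'   extent or where any contributing cell is no-data.
#' @export
bathyValue <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "bathymetryGrid"))
  gx <- grid$lon; gy <- grid$lat; z <- grid$z
  n <- length(lon)
  out <- rep(NA_real_, n)
  ix <- findInterval(lon, gx)
  iy <- findInterval(lat, gy)
  ok <- ix >= 1 & ix < length(gx) & iy >= 1 & iy < length(gy)
  # points between the outermost cell centres and the extent edge clamp
  inext <- lon >= gx[1] - grid$cellsize / 2 & lon <= gx[length(gx)] + grid$cellsize / 2 &
    lat >= gy[1] - grid$cellsize / 2 & lat <= gy[length(gy)] + grid$cellsize / 2
  edge <- inext & !ok
  for (i in which(ok)) {
    x1 <- gx[ix[i]]; x2 <- gx[ix[i] + 1]
    y1 <- gy[iy[i]]; y2 <- gy[iy[i] + 1]
    q <- z[ix[i] + 0:1, iy[i] + 0:1]
    if (anyNA(q)) next
    tx <- (lon[i] - x1) / (x2 - x1); ty <- (lat[i] - y1) / (y2 - y1)
    out[i] <- q[1, 1] * (1 - tx) * (1 - ty) + q[2, 1] * tx * (1 - ty) +
      q[1, 2] * (1 - tx) * ty + q[2, 2] * tx * ty
  }
  # clamp edge points to the nearest cell centre value
  for (i in which(edge)) {
    jx <- which.min(abs(gx - lon[i])); jy <- which.min(abs(gy - lat[i]))
    out[i] <- z[jx, jy]
  }
  out
}

#' @export
print.bathymetryGrid <- function(x, ...) {
  cat("bathymetryGrid:", length(x$lon), "x", length(x$lat), "cells,",
      "cellsize", x$cellsize, "deg\n")
  cat("  extent lon [", min(x$lon), ",", max(x$lon), "] lat [",
      min(x$lat), ",", max(x$lat), "]\n")
  cat("  elevation range", paste(range(x$z, na.rm = TRUE), collapse = " .. "),
      "m;", sum(is.na(x$z)), "no-data cells\n")
  invisible(x)
}
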