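# Regular lat/lon daily raster stacks and land masks.
#
# Cells follow the half-open convention [edge, edge + cell_size): a point
# lying exactly on a cell's upper edge belongs to the next cell.  Dates are
# contiguous and daily.  Values are stored as a (lat, lon, date) array with
# NA for missing (e.g. cloud-obscured) cells.

#' Construct a daily gridded environmental series
#'
#' @param values numeric array of dimension `c(length(lat), length(lon),
#'   length(dates))`; `NA` marks missing cells.
#' @param lat,lon cell-centre coordinates in signed decimal degrees,
#'   strictly increasing and regularly spaced at `cell_size`.
#' @param dates contiguous daily `Date` vector.
#' @param variable variable label, e.g. `"sst"` or `"chla"`.
#' @param cell_size grid resolution in degrees (default 0.5).
#' @return an object of class `env_grid_series`.
#' @export
env_grid_series <- function(values, lat, lon, dates, variable = "value",
                            cell_size = 0.5) {
  stop_if_not(is.array(values) && length(dim(values)) == 3L,
              "'values' must be a 3-d (lat, lon, date) array")
  stop_if_not(all(dim(values) == c(length(lat), length(lon), length(dates))),
              "dimensions of 'values' must match lat, lon, dates")
  dates <- as.Date(dates)
  stop_if_not(length(dates) == 0L ||
                all(diff(as.integer(dates)) == 1L),
              "'dates' must be contiguous daily dates")
  stop_if_not(cell_size > 0, "'cell_size' must be positive")
  structure(
    list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
         dates = dates, variable = variable, cell_size = cell_size),
    class = "env_grid_series"
  )
}

#' @export
print.env_grid_series <- function(x, ...) {
  cat(sprintf(
    "<env_grid_series '%s'>  %d x %d cells (%.2f deg), %d days (%s .. %s)\n",
    x$variable, length(x$lat), length(x$lon), x$cell_size,
    length(x$dates), format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("  lat %.2f..%.2f  lon %.2f..%.2f  missing %.1f%%\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              100 * mean(is.na(x$values))))
  invisible(x)
}

# Lower cell edges implied by centres.
cell_edges <- function(centers, cell_size) {
  c(centers - cell_size / 2, centers[length(centers)] + cell_size / 2)
}

# Half-open cell lookup: index i with edge[i] <= x < edge[i+1], NA outside.
cell_index <- function(x, centers, cell_size) {
  edges <- cell_edges(centers, cell_size)
  i <- findInterval(x, edges)
  i[i < 1L | i > length(centers) | x >= edges[length(edges)]] <- NA_integer_
  i
}

# Date index within the series; NA outside coverage.
date_index <- function(series, date) {
  i <- as.integer(as.Date(date) - series$dates[1]) + 1L
  i[i < 1L | i > length(series$dates)] <- NA_integer_
  i
}

#' Look up grid values at points and dates
#'
#' Vectorised point extraction with the half-open cell rule; returns `NA`
#' for points or dates outside the grid.
#'
#' @param series an [env_grid_series()].
#' @param lat,lon point coordinates (degrees).
#' @param date `Date` vector, recycled against the coordinates.
#' @return numeric vector of cell values.
#' @export
env_values_at <- function(series, lat, lon, date) {
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  date <- rep_len(as.Date(date), n)
  i <- cell_index(lat, series$lat, series$cell_size)
  j <- cell_index(lon, series$lon, series$cell_size)
  t <- date_index(series, date)
  d <- dim(series$values)
  li <- i + (j - 1L) * d[1] + (t - 1L) * d[1] * d[2]
  out <- rep(NA_real_, n)
  ok <- !is.na(li)
  out[ok] <- series$values[li[ok]]
  out
}

# Matrix of the `window_days` daily values preceding `date` (exclusive) at
# each point: one row per point, columns ordered oldest .. most recent.
env_window_values <- function(series, lat, lon, date, window_days = 12L) {
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  date <- rep_len(as.Date(date), n)
  i <- cell_index(lat, series$lat, series$cell_size)
  j <- cell_index(lon, series$lon, series$cell_size)
  t_end <- date_index(series, date - 1L)
  t_start <- date_index(series, date - window_days)
  if (anyNA(t_start[!is.na(i) & !is.na(j)]) ||
      anyNA(t_end[!is.na(i) & !is.na(j)])) {
    stop("covariate window extends before the start of the series",
         call. = FALSE)
  }
  d <- dim(series$values)
  offs <- matrix(rep(0:(window_days - 1L), each = n), n, window_days)
  tmat <- t_start + offs
  li <- i + (j - 1L) * d[1] + (tmat - 1L) * d[1] * d[2]
  out <- matrix(NA_real_, n, window_days)
  ok <- !is.na(li)
  out[ok] <- series$values[li[ok]]
  out
}

#' Aggregate raw pixels onto a regular analysis grid
#'
#' Bins raw (date, lat, lon, value) pixels into half-open cells of
#' `cell_size` degrees and averages the non-missing member pixels per cell
#' per day; a cell whose member pixels are all missing stays missing.
#' Cell edges are aligned to multiples of `cell_size`.
#'
#' @param raw data frame with columns `date`, `lat`, `lon`, `value`.
#' @param cell_size analysis resolution in degrees (default 0.5).
#' @param variable label stored on the result.
#' @return an [env_grid_series()].
#' @export
aggregate_to_grid <- function(raw, cell_size = 0.5, variable = "value") {
  stop_if_not(all(c("date", "lat", "lon", "value") %in% names(raw)),
              "'raw' needs columns date, lat, lon, value")
  raw$date <- as.Date(raw$date)
  lat0 <- floor(min(raw$lat) / cell_size) * cell_size
  lon0 <- floor(min(raw$lon) / cell_size) * cell_size
  nlat <- floor((max(raw$lat) - lat0) / cell_size) + 1L
  nlon <- floor((max(raw$lon) - lon0) / cell_size) + 1L
  lat_c <- lat0 + (seq_len(nlat) - 0.5) * cell_size
  lon_c <- lon0 + (seq_len(nlon) - 0.5) * cell_size
  dates <- seq(min(raw$date), max(raw$date), by = "day")
  i <- floor((raw$lat - lat0) / cell_size) + 1L
  j <- floor((raw$lon - lon0) / cell_size) + 1L
  t <- as.integer(raw$date - dates[1]) + 1L
  li <- i + (j - 1L) * nlat + (t - 1L) * nlat * nlon
  vals <- array(NA_real_, c(nlat, nlon, length(dates)))
  ok <- !is.na(raw$value)
  sums <- rowsum(raw$value[ok], li[ok])
  cnts <- rowsum(rep(1, sum(ok)), li[ok])
  idx <- as.integer(rownames(sums))
  vals[idx] <- sums / cnts
  env_grid_series(vals, lat_c, lon_c, dates, variable, cell_size)
}

#' Climatological mean field of a daily series
#'
#' Aggregates daily values to monthly means, monthly means to yearly
#' means, and yearly means to a single per-cell climatology, so that
#' unevenly missing days do not bias the long-term mean toward
#' well-observed months.
#'
#' @param series an [env_grid_series()].
#' @return data frame with columns `lat`, `lon`, `value` (one row per
#'   cell; `value` is `NA` where never observed), with the cell size kept
#'   in attribute `"cell_size"`.
#' @export
climatological_mean <- function(series) {
  d <- dim(series$values)
  ncell <- d[1] * d[2]
  m <- matrix(series$values, ncell, d[3])
  ym <- format(series$dates, "%Y-%m")
  monthly <- vapply(unique(ym), function(g) {
    rowMeans(m[, ym == g, drop = FALSE], na.rm = TRUE)
  }, numeric(ncell))
  yr <- substr(unique(ym), 1, 4)
  yearly <- vapply(unique(yr), function(g) {
    rowMeans(monthly[, yr == g, drop = FALSE], na.rm = TRUE)
  }, numeric(ncell))
  overall <- rowMeans(yearly, na.rm = TRUE)
  overall[is.nan(overall)] <- NA_real_
  out <- data.frame(
    lat = rep(series$lat, times = d[2]),
    lon = rep(series$lon, each = d[1]),
    value = overall
  )
  attr(out, "cell_size") <- series$cell_size
  attr(out, "variable") <- series$variable
  out
}

#' Rasterised land mask with a straight synthetic coastline
#'
#' The default synthetic geometry places land west of a coast meridian and
#' water east of it, so spatial constraint tests have analytic answers.
#'
#' @param bbox named list or vector with `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` in signed degrees.
#' @param cell_size mask resolution in degrees.
#' @param coast_lon longitude of the coastline; cells whose centre lies
#'   west of it are land. Defaults to the bbox mid-longitude.
#' @return an object of class `land_mask`.
#' @export
make_coast_mask <- function(bbox, cell_size = 0.5, coast_lon = NULL) {
  bbox <- as.list(bbox)
  stop_if_not(bbox$lat_max > bbox$lat_min && bbox$lon_max > bbox$lon_min,
              "degenerate bounding box")
  coast_lon <- coast_lon %||% ((bbox$lon_min + bbox$lon_max) / 2)
  nlat <- max(1L, round((bbox$lat_max - bbox$lat_min) / cell_size))
  nlon <- max(1L, round((bbox$lon_max - bbox$lon_min) / cell_size))
  lat_c <- bbox$lat_min + (seq_len(nlat) - 0.5) * cell_size
  lon_c <- bbox$lon_min + (seq_len(nlon) - 0.5) * cell_size
  land <- matrix(rep(lon_c < coast_lon, each = nlat), nlat, nlon)
  structure(list(lat = lat_c, lon = lon_c, land = land,
                 cell_size = cell_size, coast_lon = coast_lon),
            class = "land_mask")
}

#' Test whether points are in water
#'
#' Points outside the mask extent are treated as not water, so a mask also
#' acts as the domain boundary. A `NULL` mask means all-water.
#'
#' @param mask a `land_mask` or `NULL`.
#' @param lon,lat point coordinates (degrees).
#' @return logical vector.
#' @export
is_water <- function(mask, lon, lat) {
  n <- max(length(lon), length(lat))
  if (is.null(mask)) return(rep(TRUE, n))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  i <- cell_index(lat, mask$lat, mask$cell_size)
  j <- cell_index(lon, mask$lon, mask$cell_size)
  ok <- !is.na(i) & !is.na(j)
  out <- rep(FALSE, n)
  out[ok] <- !mask$land[cbind(i[ok], j[ok])]
  out
}
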