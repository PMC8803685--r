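# Plain-text interchange for gridded series and index tables.

#' Write / read an environmental series as long CSV
#'
#' Long schema `date, lat, lon, value` (missing cells omitted on write);
#' reading re-grids with [aggregate_to_grid()], which reproduces the
#' original series exactly when the CSV was written at the same cell
#' size.
#'
#' @param series an [env_grid_series()].
#' @param path file path.
#' @param cell_size,variable passed to [aggregate_to_grid()] on read.
#' @return `read_env_csv()` returns an [env_grid_series()].
#' @export
write_env_csv <- function(series, path) {
  d <- dim(series$values)
  df <- data.frame(
    date = rep(series$dates, each = d[1] * d[2]),
    lat = rep(series$lat, times = d[2] * d[3]),
    lon = rep(rep(series$lon, each = d[1]), times = d[3]),
    value = as.vector(series$values))
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path, cell_size = 0.5, variable = "value") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  aggregate_to_grid(raw, cell_size, variable)
}

#' Write / read a monthly index series as two-column CSV
#'
#' Schema `month` (`YYYY-MM`), `value`.
#'
#' @param oni_series data frame with `month` (Date) and `value`.
#' @param path file path.
#' @return `read_oni_csv()` returns the series data frame.
#' @export
write_oni_csv <- function(oni_series, path) {
  out <- data.frame(month = format(oni_series$month, "%Y-%m"),
                    value = oni_series$value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oni_csv
#' @export
read_oni_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$month <- as.Date(paste0(df$month, "-01"))
  structure(df, class = c("oni_series", "data.frame"))
}

#' Write a prey occurrence table as CSV
#'
#' @param prey_tables long prey table (`species`, `lat`, `lon`, `count`).
#' @param path file path.
#' @export
write_prey_csv <- function(prey_tables, path) {
  utils::write.csv(
    prey_tables[, c("species", "lat", "lon", "count")], path,
    row.names = FALSE)
  invisible(path)
}

#' @rdname write_prey_csv
#' @export
read_prey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$log_occurrence <- log(df$count + 1)
  df
}
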