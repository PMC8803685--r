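# Environmental covariate matching.
#
# Daily locations (real and pseudo) are matched to the gridded fields
# over the 12 days preceding each location.  The window is split into
# 6-day halves; per-half means over the available (non-cloudy) days give
# a recent mean and a "derivative" (the between-half difference) that
# captures whether conditions were warming/greening or the reverse while
# tolerating missing days.  A deviation-from-22 C covariate encodes the
# species' proposed thermal optimum, and the monthly ENSO index is joined
# by calendar month.

#' Mean and derivative of an environmental window
#'
#' The 12 days preceding `date` (exclusive) are split into an earlier
#' half (days -12..-7) and a recent half (days -6..-1). Each half is
#' averaged over its non-missing days; the derivative is the difference
#' between halves. By the default convention (`half_order =
#' "early_minus_late"`, reading "first half" as the earlier days) a
#' positive SST derivative means the water was cooling toward the
#' location date; set `half_order = "late_minus_early"` to flip the sign.
#'
#' @param series an [env_grid_series()].
#' @param lat,lon,date location(s) and date(s), vectorised.
#' @param window_days window length, split in half (default 12).
#' @param half_order `"early_minus_late"` (default) or
#'   `"late_minus_early"`.
#' @return data frame with columns `mean_recent` (mean of the recent
#'   half), `derivative`, and `usable` (`FALSE` when either half has no
#'   non-missing day, in which case both values are `NA`).
#' @export
window_derivative <- function(series, lat, lon, date, window_days = 12L,
                              half_order = c("early_minus_late",
                                             "late_minus_early")) {
  half_order <- match.arg(half_order)
  stop_if_not(window_days >= 2 && window_days %% 2 == 0,
              "'window_days' must be a positive even number")
  w <- env_window_values(series, lat, lon, date, window_days)
  h <- window_days / 2
  early <- w[, seq_len(h), drop = FALSE]
  late <- w[, h + seq_len(h), drop = FALSE]
  mean_early <- rowMeans(early, na.rm = TRUE)
  mean_late <- rowMeans(late, na.rm = TRUE)
  usable <- rowSums(!is.na(early)) > 0 & rowSums(!is.na(late)) > 0
  deriv <- if (half_order == "early_minus_late") {
    mean_early - mean_late
  } else {
    mean_late - mean_early
  }
  deriv[!usable] <- NA_real_
  mean_late[!usable] <- NA_real_
  data.frame(mean_recent = mean_late, derivative = deriv, usable = usable)
}

#' Deviation of recent SST from the thermal optimum isotherm
#'
#' @param mean_recent_6d_sst recent 6-day mean SST, degrees C.
#' @param isotherm_c reference isotherm (default 22, the species'
#'   proposed thermal optimum).
#' @return signed difference in degrees C (positive = warmer than the
#'   optimum).
#' @export
sst_optimal <- function(mean_recent_6d_sst, isotherm_c = 22) {
  mean_recent_6d_sst - isotherm_c
}

#' Join the monthly ENSO index to dates
#'
#' Classifies phase by the +/-0.5 C event thresholds, strict on both
#' sides: cold-phase (La Nina) months have index < -0.5, warm-phase
#' (El Nino) months > 0.5, everything else (including exactly +/-0.5) is
#' neutral.
#'
#' @param date `Date` vector.
#' @param oni_series data frame with columns `month` (first-of-month
#'   `Date`) and `value`, e.g. from [gen_oni_series()].
#' @return data frame with columns `oni` and `phase` (factor `la_nina`,
#'   `neutral`, `el_nino`).
#' @export
join_oni <- function(date, oni_series) {
  m <- as.Date(format(as.Date(date), "%Y-%m-01"))
  idx <- match(m, as.Date(oni_series$month))
  if (anyNA(idx)) {
    stop("date(s) outside the coverage of the ONI series", call. = FALSE)
  }
  v <- oni_series$value[idx]
  phase <- factor(ifelse(v < -0.5, "la_nina",
                         ifelse(v > 0.5, "el_nino", "neutral")),
                  levels = c("la_nina", "neutral", "el_nino"))
  data.frame(oni = v, phase = phase)
}

#' Build the presence/pseudo-absence covariate table
#'
#' One row per real daily location (`presence = 1`) and per retained
#' pseudo-track daily location (`presence = 0`), with window-derivative
#' covariates for SST and chlorophyll-a, the deviation of recent SST from
#' the thermal optimum, the monthly ENSO index, calendar month, marine
#' region of the row's latitude, and the animal's biological class and
#' tagging region. Rows with any unusable covariate window are kept but
#' flagged `usable = FALSE` and should be excluded from fitting.
#'
#' @param tracks annotated daily real tracks (see [annotate_track()]).
#' @param pseudo_sets list of `pseudo_track_set` objects (or `NULL` for
#'   presences only).
#' @param env_sst,env_chla [env_grid_series()] stacks.
#' @param oni_series monthly index series.
#' @param window_days,isotherm_c,half_order covariate configuration,
#'   passed to [window_derivative()] and [sst_optimal()].
#' @return data frame of covariate rows.
#' @export
build_covariate_table <- function(tracks, pseudo_sets, env_sst, env_chla,
                                  oni_series, window_days = 12L,
                                  isotherm_c = 22,
                                  half_order = "early_minus_late") {
  bio <- tracks[!duplicated(tracks$animal_id),
                c("animal_id", "sex", "tl_cm", "class", "tagging_region")]
  real <- data.frame(
    animal_id = tracks$animal_id, date = tracks$date, lat = tracks$lat,
    lon = tracks$lon, presence = 1L,
    max_depth_m = if ("max_depth_m" %in% names(tracks)) {
      tracks$max_depth_m
    } else NA_real_)
  rows <- real
  if (!is.null(pseudo_sets) && length(pseudo_sets) > 0) {
    ps <- do.call(rbind, lapply(pseudo_sets, function(s) s$tracks))
    pseudo <- data.frame(
      animal_id = ps$animal_id, date = ps$date, lat = ps$lat, lon = ps$lon,
      presence = 0L, max_depth_m = NA_real_)
    rows <- rbind(rows, pseudo)
  }
  rows <- merge(rows, bio, by = "animal_id", sort = FALSE)
  sstw <- window_derivative(env_sst, rows$lat, rows$lon, rows$date,
                            window_days, half_order)
  chlw <- window_derivative(env_chla, rows$lat, rows$lon, rows$date,
                            window_days, half_order)
  oni <- join_oni(rows$date, oni_series)
  rows$derivative_sst <- sstw$derivative
  rows$derivative_chla <- chlw$derivative
  rows$sst_optimal <- sst_optimal(sstw$mean_recent, isotherm_c)
  rows$oni <- oni$oni
  rows$oni_phase <- oni$phase
  rows$month <- as.integer(format(rows$date, "%m"))
  rows$year <- factor(format(rows$date, "%Y"))
  rows$region <- assign_region(rows$lat)
  rows$usable <- sstw$usable & chlw$usable
  if (!any(rows$usable)) {
    warning("no usable covariate rows (all environmental windows empty)")
  }
  rows
}
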