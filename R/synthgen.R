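# Synthetic-data generators with known ground truth.
#
# Real inputs to this kind of analysis (remote-sensing temperature and
# chlorophyll fields, a basin-scale climate index, telemetry tracks, and
# per-species prey occurrence grids) are rarely redistributable, so every
# downstream stage is validated against generators whose structural
# parameters -- gradients, niches, thermal optima, class composition --
# are known exactly.

#' Parameters of a synthetic daily environmental field
#'
#' Defaults describe a coastal eastern-boundary study region: a ~9.5
#' degree wide strip from 40 S to 8 S at half-degree resolution, sea
#' surface temperature near 22.5 C at the mid-latitude with a 0.35 C per
#' degree latitudinal gradient, a 2 C seasonal cycle, 0.3 C observation
#' noise and 5% missingness from cloud cover.
#'
#' @param lat_min,lat_max,lon_min,lon_max bounding box, signed degrees.
#' @param cell_size grid resolution in degrees.
#' @param t0,t1 first and last day of the series.
#' @param base_mean field value at the bbox mid-latitude (variable units).
#' @param lat_gradient change per degree of latitude moving north.
#' @param seasonal_amplitude amplitude of the day-of-year sine (units).
#' @param trend linear change in units per year.
#' @param noise_sd i.i.d. Gaussian noise sd per cell-day.
#' @param missing_rate fraction of cell-days set missing, in `[0, 1)`.
#' @return a list of class `env_field_params`.
#' @export
env_field_params <- function(lat_min = -40, lat_max = -8,
                             lon_min = 152.5, lon_max = 162,
                             cell_size = 0.5,
                             t0 = as.Date("2019-01-01"),
                             t1 = as.Date("2019-12-31"),
                             base_mean = 22.5, lat_gradient = 0.35,
                             seasonal_amplitude = 2, trend = 0,
                             noise_sd = 0.3, missing_rate = 0.05) {
  stop_if_not(cell_size > 0, "'cell_size' must be positive")
  stop_if_not(lat_max > lat_min && lon_max > lon_min,
              "degenerate bounding box (zero area)")
  t0 <- as.Date(t0); t1 <- as.Date(t1)
  stop_if_not(t1 >= t0, "'t1' must not precede 't0'")
  stop_if_not(missing_rate >= 0 && missing_rate < 1,
              "'missing_rate' must be in [0, 1)")
  structure(list(lat_min = lat_min, lat_max = lat_max, lon_min = lon_min,
                 lon_max = lon_max, cell_size = cell_size, t0 = t0, t1 = t1,
                 base_mean = base_mean, lat_gradient = lat_gradient,
                 seasonal_amplitude = seasonal_amplitude, trend = trend,
                 noise_sd = noise_sd, missing_rate = missing_rate),
            class = "env_field_params")
}

#' Generate a synthetic daily gridded field
#'
#' Cell value on a given day is
#' `base_mean + lat_gradient * (lat - lat_ref) + seasonal_amplitude *
#' sin(2 * pi * doy / 365) + trend * years_elapsed + noise`, with
#' `lat_ref` the bbox mid-latitude and leap days sharing day-of-year 365.
#' A `missing_rate` fraction of cell-days is then masked uniformly at
#' random.
#'
#' @param params an [env_field_params()].
#' @param seed integer seed; identical seeds give identical stacks.
#' @param variable label for the series.
#' @return an [env_grid_series()].
#' @export
gen_env_series <- function(params, seed = NULL, variable = "sst") {
  if (!is.null(seed)) {
    return(with_seed_if(seed, gen_env_series(params, NULL, variable)))
  }
  stop_if_not(inherits(params, "env_field_params"),
              "'params' must come from env_field_params()")
  p <- params
  nlat <- max(1L, round((p$lat_max - p$lat_min) / p$cell_size))
  nlon <- max(1L, round((p$lon_max - p$lon_min) / p$cell_size))
  lat_c <- p$lat_min + (seq_len(nlat) - 0.5) * p$cell_size
  lon_c <- p$lon_min + (seq_len(nlon) - 0.5) * p$cell_size
  dates <- seq(p$t0, p$t1, by = "day")
  lat_ref <- (p$lat_min + p$lat_max) / 2
  doy <- pmin(as.POSIXlt(dates)$yday + 1L, 365L)
  yrs <- as.numeric(dates - dates[1]) / 365.25
  day_part <- p$seasonal_amplitude * sin(2 * pi * doy / 365) + p$trend * yrs
  lat_part <- p$base_mean + p$lat_gradient * (lat_c - lat_ref)
  vals <- array(rep(lat_part, times = nlon * length(dates)),
                c(nlat, nlon, length(dates)))
  vals <- vals + rep(day_part, each = nlat * nlon)
  n <- length(vals)
  if (p$noise_sd > 0) vals <- vals + stats::rnorm(n, 0, p$noise_sd)
  if (p$missing_rate > 0) vals[stats::runif(n) < p$missing_rate] <- NA_real_
  env_grid_series(vals, lat_c, lon_c, dates, variable, p$cell_size)
}

#' Generate an ENSO-like monthly oscillation index
#'
#' A monthly sinusoid of the given amplitude and period plus Gaussian
#' noise. With the defaults (amplitude 1.2 C, 48-month period) the index
#' crosses the +/-0.5 event thresholds in both directions, so warm-phase,
#' cold-phase and neutral months all occur.
#'
#' @param t0,t1 dates bracketing the series (expanded to whole months).
#' @param amplitude sinusoid amplitude in degrees C anomaly.
#' @param period_months oscillation period; must be at least 2.
#' @param noise_sd monthly noise sd.
#' @param seed integer seed.
#' @return data frame of class `oni_series` with columns `month` (first
#'   day of month) and `value`.
#' @export
gen_oni_series <- function(t0, t1, amplitude = 1.2, period_months = 48L,
                           noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed_if(
      seed, gen_oni_series(t0, t1, amplitude, period_months, noise_sd, NULL)))
  }
  stop_if_not(period_months >= 2, "'period_months' must be >= 2")
  m0 <- as.Date(format(as.Date(t0), "%Y-%m-01"))
  m1 <- as.Date(format(as.Date(t1), "%Y-%m-01"))
  months <- seq(m0, m1, by = "month")
  k <- seq_along(months) - 1L
  value <- amplitude * sin(2 * pi * k / period_months) +
    stats::rnorm(length(k), 0, noise_sd)
  structure(data.frame(month = months, value = value),
            class = c("oni_series", "data.frame"))
}

#' Movement-preference parameters for one biological class
#'
#' @param thermal_optimum preferred water temperature, degrees C.
#' @param thermal_sd tolerance (sd of the Gaussian preference kernel);
#'   `Inf` means no thermal preference.
#' @param step_scale mean daily displacement, km.
#' @param directional_persistence in `[0, 1)`: 0 gives diffuse turning,
#'   values near 1 give nearly straight paths.
#' @return a list of class `preference_params`.
#' @export
preference_params <- function(thermal_optimum = 22, thermal_sd = 3,
                              step_scale = 30, directional_persistence = 0.3) {
  stop_if_not(thermal_sd > 0, "'thermal_sd' must be positive")
  stop_if_not(step_scale > 0, "'step_scale' must be positive")
  stop_if_not(directional_persistence >= 0 && directional_persistence < 1,
              "'directional_persistence' must be in [0, 1)")
  structure(list(thermal_optimum = thermal_optimum, thermal_sd = thermal_sd,
                 step_scale = step_scale,
                 directional_persistence = directional_persistence),
            class = "preference_params")
}

# Class-consistent sex and total length.  Maturity thresholds: 326 cm for
# females, 297 cm for males; lengths drawn uniformly within the class's
# slice of the observed 150-386 cm range.
class_biology <- function(class) {
  sex <- ifelse(grepl("female$", class), "female", "male")
  lo <- ifelse(class == "juvenile_female", 150,
        ifelse(class == "adult_female", 326,
        ifelse(class == "juvenile_male", 150, 297)))
  hi <- ifelse(class == "juvenile_female", 326,
        ifelse(class == "adult_female", 386,
        ifelse(class == "juvenile_male", 297, 386)))
  tl <- lo + stats::runif(length(class)) * (hi - lo)
  data.frame(sex = sex, tl_cm = tl)
}

# One CRW step proposal: candidate headings drawn from the turning kernel,
# endpoint thermally weighted; returns NULL when no candidate is viable.
propose_step <- function(lon, lat, heading, step_km, turn_sd, env, date,
                         pref, mask, n_candidates) {
  turns <- stats::rnorm(n_candidates, 0, turn_sd)
  heads <- heading + turns
  new_lat <- lat + step_km * cos(heads) / KM_PER_DEG
  new_lon <- lon + step_km * sin(heads) /
    (KM_PER_DEG * cos(lat * pi / 180))
  ok <- is_water(mask, new_lon, new_lat) &
    new_lat >= min(env$lat) - env$cell_size / 2 &
    new_lat <  max(env$lat) + env$cell_size / 2 &
    new_lon >= min(env$lon) - env$cell_size / 2 &
    new_lon <  max(env$lon) + env$cell_size / 2
  if (!any(ok)) return(NULL)
  if (is.finite(pref$thermal_sd)) {
    sst <- env_values_at(env, new_lat, new_lon, rep(date, n_candidates))
    w <- exp(-(sst - pref$thermal_optimum)^2 / (2 * pref$thermal_sd^2))
    w[is.na(w)] <- 0
  } else {
    w <- rep(1, n_candidates)
  }
  w[!ok] <- 0
  if (all(w == 0)) {
    w[ok] <- 1  # all viable headings equally (un)attractive, e.g. cloud
  }
  pick <- sample.int(n_candidates, 1L, prob = w)
  list(lon = new_lon[pick], lat = new_lat[pick], heading = heads[pick])
}

#' Generate thermally biased synthetic tracks
#'
#' Animals follow a correlated random walk (gamma step lengths with mean
#' `step_scale`, wrapped-Gaussian turning) whose heading choice is biased
#' toward candidate end points with temperature near the class's thermal
#' optimum: each candidate heading is weighted by
#' `exp(-(SST - thermal_optimum)^2 / (2 * thermal_sd^2))`. Positions stay
#' inside the environmental bbox and off the land mask. Each animal
#' carries a sex and total length consistent with its biological class.
#'
#' @param n_animals number of animals.
#' @param class_mix named proportions over
#'   `c("juvenile_female", "adult_female", "juvenile_male", "adult_male")`;
#'   must sum to 1.
#' @param env an [env_grid_series()] of SST covering the simulation days.
#' @param pref a [preference_params()] applied to all classes, or a named
#'   list with one per class.
#' @param land_mask optional [make_coast_mask()] result; animals never
#'   enter land cells.
#' @param n_days track length in days (daily positions).
#' @param t0 first day; defaults to the start of `env`.
#' @param start optional `c(lon, lat)` start; defaults to a random water
#'   cell centre per animal.
#' @param n_candidates candidate headings per step.
#' @param seed integer seed.
#' @return data frame of daily locations with columns `animal_id`, `sex`,
#'   `tl_cm`, `class`, `date`, `lon`, `lat`, `source`, `max_depth_m`.
#' @export
gen_tracks <- function(n_animals, class_mix, env, pref, land_mask = NULL,
                       n_days = 100, t0 = NULL, start = NULL,
                       n_candidates = 12L, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed_if(seed, gen_tracks(n_animals, class_mix, env, pref,
                                         land_mask, n_days, t0, start,
                                         n_candidates, NULL)))
  }
  stop_if_not(length(env$dates) >= 2, "'env' must cover at least 2 days")
  stop_if_not(abs(sum(class_mix) - 1) < 1e-8, "'class_mix' must sum to 1")
  t0 <- as.Date(t0 %||% env$dates[1])
  dates <- t0 + 0:(n_days - 1L)
  stop_if_not(all(!is.na(date_index(env, dates))),
              "'env' does not cover the simulation period")
  classes <- sample(names(class_mix), n_animals, replace = TRUE,
                    prob = as.numeric(class_mix))
  bio <- class_biology(classes)
  per_class_pref <- function(cl) {
    if (inherits(pref, "preference_params")) pref else pref[[cl]]
  }
  # water cell centres available as start points
  grid_lat <- rep(env$lat, times = length(env$lon))
  grid_lon <- rep(env$lon, each = length(env$lat))
  wet <- is_water(land_mask, grid_lon, grid_lat)
  stop_if_not(any(wet), "no water cells available for track starts")
  out <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    pp <- per_class_pref(classes[a])
    turn_sd <- pi * (1 - pp$directional_persistence)
    if (is.null(start)) {
      s <- sample(which(wet), 1L)
      lon <- grid_lon[s]; lat <- grid_lat[s]
    } else {
      lon <- start[1]; lat <- start[2]
    }
    heading <- stats::runif(1, -pi, pi)
    lons <- numeric(n_days); lats <- numeric(n_days)
    lons[1] <- lon; lats[1] <- lat
    for (d in 2:n_days) {
      step <- NULL
      for (try in 1:50) {
        s_km <- stats::rgamma(1, shape = 5, rate = 5 / pp$step_scale)
        step <- propose_step(lons[d - 1], lats[d - 1], heading, s_km,
                             turn_sd, env, dates[d], pp, land_mask,
                             n_candidates)
        if (!is.null(step)) break
      }
      if (is.null(step)) {  # boxed in: hold position
        lons[d] <- lons[d - 1]; lats[d] <- lats[d - 1]
      } else {
        lons[d] <- step$lon; lats[d] <- step$lat; heading <- step$heading
      }
    }
    out[[a]] <- data.frame(
      animal_id = sprintf("A%03d", a), sex = bio$sex[a],
      tl_cm = bio$tl_cm[a], class = classes[a], date = dates,
      lon = lons, lat = lats, source = "satellite",
      max_depth_m = NA_real_)
  }
  do.call(rbind, out)
}

#' Define a prey species' thermal niche
#'
#' @param species_id species label.
#' @param niche_center niche centre temperature, degrees C.
#' @param niche_width niche sd, degrees C.
#' @param max_occurrence expected records per cell at the niche centre
#'   (or everywhere, for temperature-insensitive species).
#' @param temperature_sensitive if `FALSE` the species' expected
#'   occurrence is spatially uniform, emulating taxa whose distributions
#'   show no thermal signal.
#' @return a list of class `prey_niche`.
#' @export
prey_niche <- function(species_id, niche_center = 24, niche_width = 2,
                       max_occurrence = 20, temperature_sensitive = TRUE) {
  stop_if_not(niche_width > 0, "'niche_width' must be positive")
  stop_if_not(max_occurrence >= 0, "'max_occurrence' must be >= 0")
  structure(list(species_id = species_id, niche_center = niche_center,
                 niche_width = niche_width, max_occurrence = max_occurrence,
                 temperature_sensitive = temperature_sensitive),
            class = "prey_niche")
}

#' Generate gridded prey occurrence tables
#'
#' For temperature-sensitive species the per-cell expected count is
#' `max_occurrence * exp(-(SST - niche_center)^2 / (2 * niche_width^2))`;
#' insensitive species have a spatially uniform expectation of
#' `max_occurrence`. Counts are Poisson draws. Cells with missing mean
#' SST are dropped.
#'
#' @param niches list of [prey_niche()] objects.
#' @param mean_sst_grid climatological mean SST per cell, as returned by
#'   [climatological_mean()] (columns `lat`, `lon`, `value`).
#' @param seed integer seed.
#' @return data frame with columns `species`, `lat`, `lon`, `count`,
#'   `log_occurrence` (`log(count + 1)`).
#' @export
gen_prey_tables <- function(niches, mean_sst_grid, seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed_if(seed, gen_prey_tables(niches, mean_sst_grid, NULL)))
  }
  if (inherits(niches, "prey_niche")) niches <- list(niches)
  g <- mean_sst_grid[!is.na(mean_sst_grid$value), c("lat", "lon", "value")]
  out <- lapply(niches, function(nc) {
    lambda <- if (nc$temperature_sensitive) {
      nc$max_occurrence *
        exp(-(g$value - nc$niche_center)^2 / (2 * nc$niche_width^2))
    } else {
      rep(nc$max_occurrence, nrow(g))
    }
    data.frame(species = nc$species_id, lat = g$lat, lon = g$lon,
               count = stats::rpois(nrow(g), lambda))
  })
  out <- do.call(rbind, out)
  out$log_occurrence <- log(out$count + 1)
  out
}
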