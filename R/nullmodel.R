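# Constrained correlated-random-walk pseudo-absence null model.
#
# For each tracked animal, simulated tracks are built from the animal's
# own empirical step-length and turning-angle distributions, start at the
# real tagging location, and are constrained to the minimum convex
# polygon (MCP) of the real track intersected with water.  They represent
# where the animal could plausibly have been given its movement capacity,
# and supply the absences for the occurrence models.

#' Empirical step-length and turning-angle distributions of a track
#'
#' Step lengths are great-circle (haversine) distances between
#' consecutive daily positions, in km; turning angles are signed changes
#' in heading between consecutive steps, wrapped to `(-pi, pi]`.
#'
#' @param track one animal's daily track (data frame with `lon`, `lat`,
#'   ordered by date), at least 3 locations.
#' @return list of class `step_turn_distribution` with elements
#'   `step_lengths_km` (n-1 values) and `turning_angles_rad` (n-2).
#' @export
empirical_distributions <- function(track) {
  stop_if_not(nrow(track) >= 3,
              "need at least 3 locations to define a turning angle")
  p <- as.matrix(track[, c("lon", "lat")])
  steps <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                    p[-1, , drop = FALSE]) / 1000
  bear <- geosphere::bearing(p[-nrow(p), , drop = FALSE],
                             p[-1, , drop = FALSE]) * pi / 180
  turns <- wrap_angle(diff(bear))
  structure(list(step_lengths_km = steps, turning_angles_rad = turns),
            class = "step_turn_distribution")
}

#' Minimum convex polygon of a track
#'
#' @param track data frame with `lon`, `lat`; at least 3 non-collinear
#'   locations.
#' @return matrix of hull vertices (columns `lon`, `lat`) in
#'   counter-clockwise order, not closed.
#' @export
mcp <- function(track) {
  p <- unique(as.matrix(track[, c("lon", "lat")]))
  stop_if_not(nrow(p) >= 3, "need at least 3 distinct locations for an MCP")
  h <- rev(grDevices::chull(p))  # chull is clockwise; reverse to CCW
  hull <- p[h, , drop = FALSE]
  # degenerate (collinear) input has zero area
  area <- polygon_area(hull)
  stop_if_not(area > 0, "locations are collinear; MCP is degenerate")
  hull
}

# Shoelace area of a (lon, lat) polygon in square degrees.
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Point-in-convex-polygon test (vertices CCW, not closed).
in_hull <- function(hull, lon, lat, eps = 1e-9) {
  n <- nrow(hull)
  inside <- rep(TRUE, length(lon))
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[if (k == n) 1L else k + 1L, ]
    cross <- (b[1] - a[1]) * (lat - a[2]) - (b[2] - a[2]) * (lon - a[1])
    inside <- inside & cross >= -eps
  }
  inside
}

#' Simulate constrained pseudo-tracks for one animal
#'
#' Each of `n_sim` simulations starts at the animal's real tagging
#' location with initial heading toward its second real location. Every
#' step independently resamples a (step length, turning angle) pair from
#' the empirical distributions; a proposed position outside the MCP of
#' the real track, on land, or outside the mask extent is rejected and
#' the pair redrawn up to `max_attempts_per_step` times, after which the
#' animal holds its previous position for that day (keeping every
#' simulated track the same length as the real one). Only the first
#' `n_keep` simulations are retained for modelling — enough, in this
#' design, for the matched environmental covariates to stabilise.
#'
#' @param track one animal's daily track (>= 3 locations, columns
#'   `animal_id`, `date`, `lon`, `lat`).
#' @param land_mask optional [make_coast_mask()] result (or `NULL` for
#'   all-water).
#' @param n_sim simulations computed per animal (default 100).
#' @param n_keep simulations retained (default 45).
#' @param max_attempts_per_step redraw budget per step (default 100).
#' @param constrain_mcp keep simulations inside the real track's MCP
#'   (default `TRUE`); set `FALSE` (with a `NULL` mask) to disable all
#'   rejection, e.g. to verify that simulations resample the empirical
#'   kernels.
#' @param seed integer seed; fixed seed gives identical sets.
#' @return object of class `pseudo_track_set`: list with `animal_id`,
#'   `n_simulated`, `n_retained`, `hull`, and `tracks` (a data frame of
#'   all retained positions with columns `animal_id`, `sim_id`, `date`,
#'   `lon`, `lat`, `is_pseudo`).
#' @export
simulate_pseudo_tracks <- function(track, land_mask = NULL, n_sim = 100L,
                                   n_keep = 45L,
                                   max_attempts_per_step = 100L,
                                   constrain_mcp = TRUE,
                                   seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed_if(
      seed, simulate_pseudo_tracks(track, land_mask, n_sim, n_keep,
                                   max_attempts_per_step, constrain_mcp,
                                   NULL)))
  }
  stop_if_not(n_keep <= n_sim, "'n_keep' must not exceed 'n_sim'")
  stop_if_not(nrow(track) >= 3, "track must have at least 3 locations")
  emp <- empirical_distributions(track)
  hull <- mcp(track)
  n_pos <- nrow(track)
  start <- c(track$lon[1], track$lat[1])
  init_heading <- geosphere::bearing(start,
                                     c(track$lon[2], track$lat[2])) * pi / 180
  sims <- vector("list", n_sim)
  any_step1 <- FALSE
  for (s in seq_len(n_sim)) {
    lons <- numeric(n_pos); lats <- numeric(n_pos)
    lons[1] <- start[1]; lats[1] <- start[2]
    heading <- init_heading
    for (i in 2:n_pos) {
      placed <- FALSE
      for (att in seq_len(max_attempts_per_step)) {
        step <- sample(emp$step_lengths_km, 1L)
        turn <- sample(emp$turning_angles_rad, 1L)
        h <- heading + turn
        nlat <- lats[i - 1] + step * cos(h) / KM_PER_DEG
        nlon <- lons[i - 1] + step * sin(h) /
          (KM_PER_DEG * cos(lats[i - 1] * pi / 180))
        if ((!constrain_mcp || in_hull(hull, nlon, nlat)) &&
            is_water(land_mask, nlon, nlat)) {
          lons[i] <- nlon; lats[i] <- nlat; heading <- h
          placed <- TRUE
          break
        }
      }
      if (!placed) {  # truncate: hold the last valid position
        lons[i] <- lons[i - 1]; lats[i] <- lats[i - 1]
      } else if (i == 2L) {
        any_step1 <- TRUE
      }
    }
    sims[[s]] <- data.frame(
      animal_id = track$animal_id[1], sim_id = s, date = track$date,
      lon = lons, lat = lats, is_pseudo = 1L)
  }
  if (!any_step1) {
    stop("unreachable geometry: no simulation could take its first step",
         call. = FALSE)
  }
  kept <- do.call(rbind, sims[seq_len(n_keep)])
  structure(list(animal_id = track$animal_id[1], n_simulated = n_sim,
                 n_retained = n_keep, hull = hull, tracks = kept),
            class = "pseudo_track_set")
}

#' @export
print.pseudo_track_set <- function(x, ...) {
  cat(sprintf("<pseudo_track_set %s>  %d/%d simulations retained, %d positions each\n",
              x$animal_id, x$n_retained, x$n_simulated,
              nrow(x$tracks) / x$n_retained))
  invisible(x)
}

#' Covariate stabilisation across increasing numbers of simulations
#'
#' For each k in `k_values`, the mean of each matched environmental
#' covariate over the first k simulated tracks. Plotting these running
#' means against k shows where adding further simulations stops moving
#' the covariate distributions, guiding the choice of `n_keep`.
#'
#' @param pseudo_set a `pseudo_track_set` (retained simulations are
#'   indexed by `sim_id`).
#' @param env named list of [env_grid_series()] objects to match.
#' @param k_values increasing numbers of simulations to average over.
#' @return data frame with columns `k`, `variable`, `mean_value`.
#' @export
covariate_stabilisation <- function(pseudo_set, env, k_values) {
  tr <- pseudo_set$tracks
  out <- list()
  for (v in names(env)) {
    vals <- env_values_at(env[[v]], tr$lat, tr$lon, tr$date)
    per_sim <- tapply(vals, tr$sim_id, mean, na.rm = TRUE)
    sims_avail <- as.integer(names(per_sim))
    means <- vapply(k_values, function(k) {
      mean(per_sim[sims_avail <= k], na.rm = TRUE)
    }, numeric(1))
    out[[v]] <- data.frame(k = k_values, variable = v, mean_value = means)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write pseudo-tracks in the track CSV schema
#'
#' Adds `sim_id` and `is_pseudo = 1` columns to the standard schema.
#'
#' @param pseudo_set a `pseudo_track_set`.
#' @param path file path.
#' @export
write_pseudo_tracks_csv <- function(pseudo_set, path) {
  utils::write.csv(pseudo_set$tracks, path, row.names = FALSE)
  invisible(path)
}
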