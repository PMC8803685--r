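# Shared fixture builders and independent oracles. All fixtures are
# generated in code; no data files.

# Noise-free single-purpose environmental stacks -------------------------

flat_env <- function(value = 22, n_days = 30, lat_min = -30, lat_max = -24,
                     lon_min = 153, lon_max = 158, cell_size = 0.5,
                     t0 = as.Date("2019-01-01"), variable = "sst") {
  gen_env_series(env_field_params(
    lat_min = lat_min, lat_max = lat_max, lon_min = lon_min,
    lon_max = lon_max, cell_size = cell_size,
    t0 = t0, t1 = t0 + n_days - 1, base_mean = value, lat_gradient = 0,
    seasonal_amplitude = 0, trend = 0, noise_sd = 0, missing_rate = 0),
    seed = 1, variable = variable)
}

gradient_env <- function(gradient = 0.35, base = 22.5, n_days = 30,
                         lat_min = -40, lat_max = -8, lon_min = 152.5,
                         lon_max = 162, t0 = as.Date("2019-01-01"),
                         noise_sd = 0, missing_rate = 0) {
  gen_env_series(env_field_params(
    lat_min = lat_min, lat_max = lat_max, lon_min = lon_min,
    lon_max = lon_max, t0 = t0, t1 = t0 + n_days - 1,
    base_mean = base, lat_gradient = gradient, seasonal_amplitude = 0,
    trend = 0, noise_sd = noise_sd, missing_rate = missing_rate),
    seed = 2, variable = "sst")
}

# A minimal single-animal daily track from coordinate vectors.
make_track <- function(lon, lat, id = "T01", sex = "female", tl = 300,
                       t0 = as.Date("2019-02-01")) {
  data.frame(animal_id = id, sex = sex, tl_cm = tl,
             date = t0 + seq_along(lon) - 1, lon = lon, lat = lat,
             source = "satellite", max_depth_m = NA_real_,
             stringsAsFactors = FALSE)
}

# A climatological-mean-style SST grid built directly (cells x deg apart).
make_sst_grid <- function(sst, cell_size = 0.5) {
  n <- length(sst)
  ncol <- ceiling(sqrt(n))
  lat <- -40 + cell_size * ((seq_len(n) - 1) %% ncol) + cell_size / 2
  lon <- 153 + cell_size * ((seq_len(n) - 1) %/% ncol) + cell_size / 2
  out <- data.frame(lat = lat, lon = lon, value = sst)
  attr(out, "cell_size") <- cell_size
  out
}

# Independent great-circle oracle (haversine on the same 6378.137 km
# radius sphere the implementation's distance backend uses).
haversine_km <- function(lon1, lat1, lon2, lat2, r = 6378.137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# O(n^3) convex-hull oracle: a point is a hull vertex iff it is not
# strictly inside (or on the boundary of) a triangle of three others.
brute_hull_vertices <- function(p) {
  n <- nrow(p)
  inside <- rep(FALSE, n)
  idx <- utils::combn(n, 3)
  for (col in seq_len(ncol(idx))) {
    tri <- p[idx[, col], , drop = FALSE]
    d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
      (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
    if (abs(d) < 1e-12) next
    a <- ((tri[2, 2] - tri[3, 2]) * (p[, 1] - tri[3, 1]) +
            (tri[3, 1] - tri[2, 1]) * (p[, 2] - tri[3, 2])) / d
    b <- ((tri[3, 2] - tri[1, 2]) * (p[, 1] - tri[3, 1]) +
            (tri[1, 1] - tri[3, 1]) * (p[, 2] - tri[3, 2])) / d
    c <- 1 - a - b
    inside <- inside | (a > 1e-9 & b > 1e-9 & c > 1e-9)
  }
  which(!inside)
}

# Point-in-convex-polygon oracle with a small outward tolerance.
point_in_hull_oracle <- function(hull, lon, lat, eps = 1e-6) {
  n <- nrow(hull)
  ok <- rep(TRUE, length(lon))
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[if (k == n) 1L else k + 1L, ]
    cross <- (b[1] - a[1]) * (lat - a[2]) - (b[2] - a[2]) * (lon - a[1])
    ok <- ok & cross >= -eps
  }
  ok
}

# Per-window brute-force derivative oracle mirroring the missing-data
# rule: per-half mean over available days, >= 1 day per half required.
brute_window <- function(series, lat, lon, date, window_days = 12L) {
  days <- date - rev(seq_len(window_days))
  v <- vapply(seq_along(days), function(i) {
    env_values_at(series, lat, lon, days[i])
  }, numeric(1))
  h <- window_days / 2
  early <- v[seq_len(h)]; late <- v[h + seq_len(h)]
  if (all(is.na(early)) || all(is.na(late))) {
    return(list(mean_recent = NA_real_, derivative = NA_real_,
                usable = FALSE))
  }
  list(mean_recent = mean(late, na.rm = TRUE),
       derivative = mean(early, na.rm = TRUE) - mean(late, na.rm = TRUE),
       usable = TRUE)
}

# Presence/pseudo-absence covariate rows with a logistic thermal
# preference peaking at sst_optimal = 0 (the thermal-optimum
# construction), mimicking a 45:1 design by its low prevalence.
make_presence_rows <- function(n = 5000, peak_sd = 2, intercept = -2) {
  x <- stats::runif(n, -8, 8)
  p <- stats::plogis(intercept - x^2 / (2 * peak_sd^2))
  data.frame(presence = stats::rbinom(n, 1, p), sst_optimal = x)
}
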