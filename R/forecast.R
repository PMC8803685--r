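# Prey-mediated habitat-suitability forecasting.
#
# The chain: per-class gridded counts of daily predator locations ->
# Poisson GLM screening of prey species (retain positive, significant
# associations) -> Gamma thermal response model per retained prey species
# -> nested comparison of a temperature-only ("partial") and a
# temperature-plus-prey ("full") predator model -> monthly projection of
# prey, then predator intensity, onto forecast temperature fields,
# averaged to yearly and decadal suitability layers.

prey_col <- function(species) paste0("prey_", make.names(species))

#' Gridded count matrix of class-specific daily locations
#'
#' @param tracks annotated daily track table (with `class` column).
#' @param class biological class to count (one of the four levels); use
#'   `NULL` to pool all classes.
#' @param template cell template: data frame with `lat`, `lon` cell
#'   centres and a `"cell_size"` attribute, e.g. from
#'   [climatological_mean()].
#' @return data frame with columns `lat`, `lon`, `count` (integer, zero
#'   where no locations fall); counts over all cells sum to the number
#'   of in-grid daily locations of the class.
#' @export
shark_count_matrix <- function(tracks, class = NULL, template) {
  cs <- attr(template, "cell_size")
  stop_if_not(!is.null(cs), "'template' needs a cell_size attribute")
  d <- if (is.null(class)) {
    tracks
  } else {
    tracks[as.character(tracks$class) == class, , drop = FALSE]
  }
  lat_c <- sort(unique(template$lat))
  lon_c <- sort(unique(template$lon))
  out <- data.frame(lat = template$lat, lon = template$lon, count = 0L)
  if (nrow(d) > 0) {
    i <- cell_index(d$lat, lat_c, cs)
    j <- cell_index(d$lon, lon_c, cs)
    ok <- !is.na(i) & !is.na(j)
    key_pts <- paste(lat_c[i[ok]], lon_c[j[ok]])
    key_cells <- paste(template$lat, template$lon)
    tab <- table(key_pts)
    m <- match(key_cells, names(tab))
    out$count <- ifelse(is.na(m), 0L, as.integer(tab[m]))
  }
  out
}

#' Screen prey species against predator counts (Poisson GLM)
#'
#' Fits one Poisson log-link GLM of per-cell predator counts on the
#' log-transformed occurrences of all prey species jointly. A species is
#' retained when its coefficient is positive and significant at
#' `p_threshold`. Near-duplicate prey columns trigger a collinearity
#' warning; non-convergence is reported.
#'
#' @param class_matrix per-cell predator counts
#'   ([shark_count_matrix()]).
#' @param prey_tables long prey table (`species`, `lat`, `lon`, `count`,
#'   `log_occurrence`), at least 2 species.
#' @param p_threshold per-species significance level (default 0.05, no
#'   multiplicity correction).
#' @return list with `retained` (character vector of species),
#'   `coefficients` (per-species estimate, se, p, retained flag), and
#'   the fitted `glm` object.
#' @export
prey_glm <- function(class_matrix, prey_tables, p_threshold = 0.05) {
  species <- unique(prey_tables$species)
  stop_if_not(length(species) >= 2, "need at least 2 prey species")
  wide <- class_matrix[, c("lat", "lon", "count")]
  for (sp in species) {
    d <- prey_tables[prey_tables$species == sp, c("lat", "lon",
                                                  "log_occurrence")]
    names(d)[3] <- prey_col(sp)
    wide <- merge(wide, d, by = c("lat", "lon"))
  }
  preds <- prey_col(species)
  cc <- stats::cor(wide[preds])
  dup <- which(abs(cc) > 0.99 & upper.tri(cc), arr.ind = TRUE)
  if (nrow(dup)) {
    warning("collinear prey predictors: ",
            paste(preds[dup[, 1]], preds[dup[, 2]],
                  sep = " ~ ", collapse = "; "))
  }
  form <- stats::as.formula(paste("count ~", paste(preds, collapse = " + ")))
  fit <- stats::glm(form, data = wide, family = stats::poisson())
  if (!fit$converged) warning("prey GLM did not converge")
  co <- summary(fit)$coefficients
  m <- match(preds, rownames(co))  # aliased predictors drop out of the fit
  coefs <- data.frame(species = species, estimate = co[m, 1],
                      se = co[m, 2], p = co[m, 4], row.names = NULL)
  coefs$retained <- !is.na(coefs$p) & coefs$p < p_threshold &
    coefs$estimate > 0
  list(retained = coefs$species[coefs$retained], coefficients = coefs,
       model = fit)
}

#' Thermal response model for one prey species
#'
#' Gamma (log link) additive model of `log(occurrence + 1)` on a smooth
#' of climatological mean SST, restricted to cells where the species was
#' recorded. A species is excluded when it has fewer than `min_positive`
#' occupied cells or when the smooth is not significant at
#' `p_threshold` (no detectable thermal signal).
#'
#' @param prey_table one species' rows of the prey table.
#' @param mean_sst_grid climatology from [climatological_mean()].
#' @param min_positive minimum occupied cells (default 30).
#' @param p_threshold smooth significance level (default 0.05).
#' @param k basis dimension of the thermal smooth.
#' @return list of class `prey_thermal_fit` with `species`, `included`,
#'   `p_value`, `n_positive` and (when fitted) the `gam` object.
#' @export
prey_thermal_model <- function(prey_table, mean_sst_grid,
                               min_positive = 30, p_threshold = 0.05,
                               k = 10) {
  sp <- unique(prey_table$species)
  stop_if_not(length(sp) == 1, "one species at a time")
  d <- merge(prey_table, mean_sst_grid, by = c("lat", "lon"))
  names(d)[names(d) == "value"] <- "sst"
  d <- d[!is.na(d$sst) & d$count > 0, , drop = FALSE]
  if (nrow(d) < min_positive) {
    warning(sprintf("'%s': only %d occupied cells (< %d); excluded",
                    sp, nrow(d), min_positive))
    return(structure(list(species = sp, included = FALSE,
                          p_value = NA_real_, n_positive = nrow(d),
                          gam = NULL),
                     class = "prey_thermal_fit"))
  }
  d$log_occ <- log(d$count + 1)
  if (stats::var(d$log_occ) < 1e-10) {
    # constant occurrence: nothing for temperature to explain
    return(structure(list(species = sp, included = FALSE,
                          p_value = NA_real_, n_positive = nrow(d),
                          gam = NULL),
                     class = "prey_thermal_fit"))
  }
  fit <- mgcv::gam(log_occ ~ s(sst, k = k), data = d,
                   family = stats::Gamma(link = "log"))
  p <- summary(fit)$s.table[1, "p-value"]
  structure(list(species = sp, included = is.finite(p) && p < p_threshold,
                 p_value = as.numeric(p), n_positive = nrow(d), gam = fit),
            class = "prey_thermal_fit")
}

#' Temperature at which a fitted prey thermal response peaks
#'
#' @param thermal_fit a [prey_thermal_model()] result with a fit.
#' @param n evaluation grid size.
#' @return SST (degrees C) maximising the predicted occurrence.
#' @export
thermal_peak <- function(thermal_fit, n = 400) {
  stop_if_not(!is.null(thermal_fit$gam), "species was not fitted")
  rng <- range(thermal_fit$gam$model$sst)
  grid <- data.frame(sst = seq(rng[1], rng[2], length.out = n))
  pred <- stats::predict(thermal_fit$gam, grid, type = "response")
  grid$sst[which.max(pred)]
}

#' Fit and compare temperature-only and temperature-plus-prey models
#'
#' The partial model is a Poisson additive model of per-cell predator
#' counts on a smooth of climatological SST; the full model adds the
#' log-occurrence of each retained prey species as a linear term. The
#' nested pair is compared by an analysis of deviance (chi-squared test
#' on the deviance drop, with degrees of freedom from the added terms).
#'
#' @param class_matrix per-cell predator counts.
#' @param mean_sst_grid climatology from [climatological_mean()].
#' @param prey_tables long prey table.
#' @param retained_prey species retained by both [prey_glm()] and
#'   [prey_thermal_model()]; empty makes the full model identical to the
#'   partial model (warned, comparison degenerate).
#' @param k basis dimension of the SST smooth.
#' @return list of class `partial_full_comparison` with `partial`,
#'   `full` (gam objects), `data`, and `comparison` (deviance explained
#'   of both, the deviance chi-squared statistic, df and p-value).
#' @export
fit_partial_and_full <- function(class_matrix, mean_sst_grid, prey_tables,
                                 retained_prey, k = 10) {
  d <- merge(class_matrix, mean_sst_grid, by = c("lat", "lon"))
  names(d)[names(d) == "value"] <- "sst"
  d <- d[!is.na(d$sst), , drop = FALSE]
  for (sp in retained_prey) {
    pt <- prey_tables[prey_tables$species == sp,
                      c("lat", "lon", "log_occurrence")]
    names(pt)[3] <- prey_col(sp)
    d <- merge(d, pt, by = c("lat", "lon"))
  }
  partial <- mgcv::gam(count ~ s(sst, k = k), data = d,
                       family = stats::poisson())
  if (length(retained_prey) == 0) {
    warning("no retained prey species: full model equals partial model")
    full <- partial
  } else {
    form <- stats::as.formula(paste(
      "count ~ s(sst, k =", k, ") +",
      paste(prey_col(retained_prey), collapse = " + ")))
    full <- mgcv::gam(form, data = d, family = stats::poisson())
  }
  dev_p <- summary(partial)$dev.expl
  dev_f <- summary(full)$dev.expl
  chisq <- max(0, stats::deviance(partial) - stats::deviance(full))
  # each added prey term is a 1-edf linear coefficient
  df <- length(retained_prey)
  p_value <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
             else NA_real_
  structure(list(
    partial = partial, full = full, data = d,
    retained_prey = retained_prey,
    comparison = list(dev_expl_partial_pct = 100 * dev_p,
                      dev_expl_full_pct = 100 * dev_f,
                      chisq = chisq, df = df, p_value = p_value)),
    class = "partial_full_comparison")
}

#' @export
print.partial_full_comparison <- function(x, ...) {
  cmp <- x$comparison
  cat(sprintf(
    "<partial_full_comparison>  partial %.1f%% vs full %.1f%% deviance explained\n",
    cmp$dev_expl_partial_pct, cmp$dev_expl_full_pct))
  cat(sprintf("  prey terms: %s\n  deviance chi-sq = %.1f on %.1f df, p = %.3g\n",
              if (length(x$retained_prey)) {
                paste(x$retained_prey, collapse = ", ")
              } else "(none)",
              cmp$chisq, cmp$df, cmp$p_value))
  invisible(x)
}

#' Project a decade of monthly habitat suitability
#'
#' For every forecast month, each retained prey species' occurrence is
#' predicted from its thermal response model at the forecast SST, and
#' the (SST, predicted prey) covariates are fed into the full predator
#' model to give a per-cell predicted intensity. Monthly layers are
#' averaged within years, and yearly layers averaged into the decadal
#' suitability map. The projection is deterministic given the fits and
#' the forecast fields.
#'
#' @param comparison a [fit_partial_and_full()] result (its full model
#'   is projected).
#' @param prey_fits named list of [prey_thermal_model()] fits covering
#'   every retained species.
#' @param forecast_sst_monthly data frame of monthly forecast SST on the
#'   analysis grid: columns `date` (first of month), `lat`, `lon`,
#'   `sst`. Cell set must match the fitting grid.
#' @return object of class `suitability_map` with `monthly`, `yearly`
#'   and `decadal` layers (long data frames of per-cell intensity).
#' @export
project_decade <- function(comparison, prey_fits, forecast_sst_monthly) {
  fc <- forecast_sst_monthly
  stop_if_not(all(c("date", "lat", "lon", "sst") %in% names(fc)),
              "'forecast_sst_monthly' needs date, lat, lon, sst")
  fit_cells <- unique(paste(comparison$data$lat, comparison$data$lon))
  fc_cells <- unique(paste(fc$lat, fc$lon))
  stop_if_not(all(fc_cells %in% fit_cells),
              "forecast grid is not aligned with the fitting grid")
  fc$date <- as.Date(fc$date)
  months <- sort(unique(fc$date))
  monthly <- lapply(months, function(m) {
    nd <- fc[fc$date == m, c("lat", "lon", "sst")]
    for (sp in comparison$retained_prey) {
      tf <- prey_fits[[sp]]
      stop_if_not(!is.null(tf) && !is.null(tf$gam),
                  sprintf("no thermal fit for retained species '%s'", sp))
      nd[[prey_col(sp)]] <- as.numeric(
        stats::predict(tf$gam, data.frame(sst = nd$sst),
                       type = "response"))
    }
    nd$intensity <- as.numeric(
      stats::predict(comparison$full, nd, type = "response"))
    nd$date <- m
    nd[, c("date", "lat", "lon", "intensity")]
  })
  monthly <- do.call(rbind, monthly)
  monthly$year <- as.integer(format(monthly$date, "%Y"))
  yearly <- stats::aggregate(intensity ~ year + lat + lon, monthly, mean)
  decadal <- stats::aggregate(intensity ~ lat + lon, yearly, mean)
  structure(list(monthly = monthly[, c("date", "lat", "lon", "intensity")],
                 yearly = yearly, decadal = decadal),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf(
    "<suitability_map>  %d months, %d years, %d cells; decadal centroid %.2f deg lat\n",
    length(unique(x$monthly$date)), length(unique(x$yearly$year)),
    nrow(x$decadal), suitability_centroid(x)))
  invisible(x)
}

#' Intensity-weighted latitudinal centroid of a suitability map
#'
#' Diagnostic for poleward shifts: the weighted mean latitude of the
#' decadal layer.
#'
#' @param map a [project_decade()] result (or any data frame with `lat`
#'   and `intensity`).
#' @return latitude in signed degrees.
#' @export
suitability_centroid <- function(map) {
  d <- if (inherits(map, "suitability_map")) map$decadal else map
  w <- sum(d$intensity)
  stop_if_not(is.finite(w) && w > 0,
              "all-zero suitability map: centroid undefined")
  sum(d$lat * d$intensity) / w
}

#' Write a suitability map as long CSV
#'
#' @param map a `suitability_map`.
#' @param path output file; the decadal layer is written, with yearly
#'   layers alongside when `layer = "yearly"`.
#' @param layer `"decadal"` (default), `"yearly"` or `"monthly"`.
#' @export
write_suitability_csv <- function(map, path, layer = "decadal") {
  utils::write.csv(map[[layer]], path, row.names = FALSE)
  invisible(path)
}
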