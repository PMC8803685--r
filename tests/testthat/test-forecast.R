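# Shared scenario: cells along a thermal gradient, prey with a known
# Gaussian niche, predator counts driven by realised prey occurrence.
prey_chain_scenario <- function(seed = 201, n_cells = 500,
                                niche_center = 24, prey_scale = 8,
                                shark_on_prey = 1.0, shark_sst_only = FALSE) {
  withr::with_seed(seed, {
    grid <- make_sst_grid(runif(n_cells, 15, 30))
    prey <- gen_prey_tables(
      list(prey_niche("turtle", niche_center, 2, prey_scale),
           prey_niche("teleost", niche_center - 2, 3, prey_scale),
           prey_niche("drifter", 22, 2, prey_scale,
                      temperature_sensitive = FALSE)),
      grid, seed = seed + 1)
    turtle <- prey[prey$species == "turtle", ]
    counts <- grid[, c("lat", "lon")]
    rate <- if (shark_sst_only) {
      exp(1.2 - (grid$value - niche_center)^2 / 8)
    } else {
      exp(-0.5 + shark_on_prey * turtle$log_occurrence)
    }
    counts$count <- rpois(n_cells, rate)
    attr(counts, "cell_size") <- attr(grid, "cell_size")
  })
  list(grid = grid, prey = prey, counts = counts)
}

test_that("count matrices conserve daily locations per cell", {
  grid <- make_sst_grid(rep(20, 25))
  tr <- annotate_track(make_track(lon = rep(grid$lon[7], 10),
                                  lat = rep(grid$lat[7], 10)))
  cm <- shark_count_matrix(tr, "juvenile_female", grid)
  expect_equal(sum(cm$count), 10)
  expect_equal(cm$count[7], 10)
  expect_true(all(cm$count[-7] == 0))

  # an empty class gives an all-zero matrix
  cm0 <- shark_count_matrix(tr, "adult_male", grid)
  expect_true(all(cm0$count == 0))

  # pooled counts over a scattered track conserve the total
  withr::with_seed(202, {
    tr2 <- annotate_track(make_track(
      lon = sample(grid$lon, 40, TRUE) + runif(40, -0.2, 0.2),
      lat = sample(grid$lat, 40, TRUE) + runif(40, -0.2, 0.2)))
  })
  cm2 <- shark_count_matrix(tr2, NULL, grid)
  in_grid <- sum(!is.na(predcast:::cell_index(tr2$lat, sort(unique(grid$lat)),
                                              0.5)) &
                 !is.na(predcast:::cell_index(tr2$lon, sort(unique(grid$lon)),
                                              0.5)))
  expect_equal(sum(cm2$count), in_grid)
})

test_that("prey screening keeps the causal species and drops the rest", {
  sc <- prey_chain_scenario(seed = 203)
  pg <- prey_glm(sc$counts, sc$prey)
  expect_true("turtle" %in% pg$retained)
  expect_false("drifter" %in% pg$retained)
  expect_true(all(c("estimate", "p", "retained") %in%
                    names(pg$coefficients)))

  # all-zero predator matrix retains nothing (and reports the
  # degenerate fit)
  zero <- sc$counts; zero$count <- 0L
  w <- capture_warnings(pg0 <- prey_glm(zero, sc$prey))
  expect_match(w, "converge", all = FALSE)
  expect_length(pg0$retained, 0)

  # duplicated prey column triggers a collinearity warning
  dup <- sc$prey[sc$prey$species == "turtle", ]
  dup$species <- "turtle_copy"
  expect_warning(prey_glm(sc$counts, rbind(sc$prey, dup)), "collinear")
})

test_that("prey thermal models recover niches and exclude non-thermal species", {
  sc <- prey_chain_scenario(seed = 204, prey_scale = 20)
  tf <- prey_thermal_model(sc$prey[sc$prey$species == "turtle", ],
                           sc$grid)
  expect_true(tf$included)
  expect_lt(abs(thermal_peak(tf) - 24), 1)

  # temperature-insensitive species excluded in the vast majority of
  # replicates (the screen's per-test level allows occasional inclusion)
  excluded <- vapply(1:30, function(s) {
    sc_s <- prey_chain_scenario(seed = 300 + s)
    !prey_thermal_model(sc_s$prey[sc_s$prey$species == "drifter", ],
                        sc_s$grid)$included
  }, logical(1))
  expect_gte(mean(excluded), 0.8)

  # constant occurrence everywhere: no thermal signal, excluded
  const <- sc$prey[sc$prey$species == "turtle", ]
  const$count <- 5L
  const$log_occurrence <- log(6)
  expect_false(prey_thermal_model(const, sc$grid)$included)

  # too few occupied cells: excluded with a warning
  sparse <- sc$prey[sc$prey$species == "turtle", ][1:40, ]
  sparse$count[1:25] <- 0L
  expect_warning(out <- prey_thermal_model(sparse, sc$grid),
                 "occupied cells")
  expect_false(out$included)
})

test_that("full models nest the partial model and split out prey signal", {
  sc <- prey_chain_scenario(seed = 205)
  cmp <- fit_partial_and_full(sc$counts, sc$grid, sc$prey, "turtle")
  cc <- cmp$comparison
  expect_gte(cc$dev_expl_full_pct, cc$dev_expl_partial_pct)
  expect_gte(cc$chisq, 0)
  expect_lt(cc$p_value, 0.01)

  # empty retained set: degenerate comparison, warned
  expect_warning(cmp0 <- fit_partial_and_full(sc$counts, sc$grid,
                                              sc$prey, character(0)),
                 "full model equals partial")
  expect_equal(cmp0$comparison$dev_expl_full_pct,
               cmp0$comparison$dev_expl_partial_pct)
})

test_that("decadal projection chains prey predictions deterministically", {
  sc <- prey_chain_scenario(seed = 206)
  pg <- prey_glm(sc$counts, sc$prey)
  tf <- list(turtle = prey_thermal_model(
    sc$prey[sc$prey$species == "turtle", ], sc$grid))
  ret <- intersect(pg$retained, "turtle")
  expect_identical(ret, "turtle")
  cmp <- fit_partial_and_full(sc$counts, sc$grid, sc$prey, ret)

  cells <- sc$grid[!is.na(sc$grid$value), ]
  months <- seq(as.Date("2021-01-01"), by = "month", length.out = 120)
  fc_flat <- do.call(rbind, lapply(months, function(m) {
    data.frame(date = m, lat = cells$lat, lon = cells$lon,
               sst = cells$value)
  }))
  map <- project_decade(cmp, tf, fc_flat)

  # identical monthly forcing: every month identical, aggregation exact
  m1 <- map$monthly[map$monthly$date == months[1], ]
  expect_equal(map$decadal$intensity[order(map$decadal$lat,
                                           map$decadal$lon)],
               m1$intensity[order(m1$lat, m1$lon)], tolerance = 1e-10)
  yearly_mean <- aggregate(intensity ~ lat + lon, map$yearly, mean)
  o1 <- order(map$decadal$lat, map$decadal$lon)
  o2 <- order(yearly_mean$lat, yearly_mean$lon)
  expect_equal(map$decadal$intensity[o1], yearly_mean$intensity[o2],
               tolerance = 1e-12)
  expect_equal(nrow(map$yearly), 10 * nrow(map$decadal))

  # deterministic given fits and forcing
  map2 <- project_decade(cmp, tf, fc_flat)
  expect_identical(map$decadal, map2$decadal)

  # misaligned forecast grid is an error
  bad <- fc_flat; bad$lon <- bad$lon + 10
  expect_error(project_decade(cmp, tf, bad), "not aligned")
})

test_that("suitability centroids flag poleward shifts under warming", {
  d <- data.frame(lat = c(-30, -24.5, -19), intensity = c(1, 2, 1))
  expect_equal(suitability_centroid(d), -24.5)
  d2 <- data.frame(lat = c(-30, -20), intensity = c(3, 0))
  expect_equal(suitability_centroid(d2), -30)
  expect_error(suitability_centroid(data.frame(lat = -20, intensity = 0)),
               "all-zero")

  # cool-niche predator: +0.3 C/yr forecast shifts the centroid poleward
  sc <- prey_chain_scenario(seed = 207, niche_center = 20)
  tf <- list(turtle = prey_thermal_model(
    sc$prey[sc$prey$species == "turtle", ], sc$grid))
  cmp <- fit_partial_and_full(sc$counts, sc$grid, sc$prey, "turtle")
  cells <- sc$grid[!is.na(sc$grid$value), ]
  # couple temperature to latitude so a shift is spatially expressed
  cells$value <- 22.5 + 0.35 * (cells$lat + 24) +
    (cells$value - mean(cells$value)) * 0.1
  months <- seq(as.Date("2021-01-01"), by = "month", length.out = 120)
  mk_fc <- function(trend) do.call(rbind, lapply(seq_along(months),
    function(k) data.frame(date = months[k], lat = cells$lat,
                           lon = cells$lon,
                           sst = cells$value + trend * (k - 1) / 12)))
  flat <- project_decade(cmp, tf, mk_fc(0))
  warm <- project_decade(cmp, tf, mk_fc(0.3))
  expect_lt(suitability_centroid(warm), suitability_centroid(flat))
})
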