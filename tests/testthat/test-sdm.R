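test_that("a known smooth signal is recovered from noisy data", {
  withr::with_seed(101, {
    n <- 2000
    x <- runif(n, -3, 3)
    truth <- sin(1.5 * x) + 0.4 * x
    d <- data.frame(y = truth + rnorm(n, 0, 0.3), sst_optimal = x)
  })
  fit <- fit_pam(model_spec("y", "gaussian",
                            fixed = smooth_term("sst_optimal")), d)
  pe <- partial_effect(fit, "sst_optimal", n = 100)
  truth_pe <- sin(1.5 * pe$x) + 0.4 * pe$x
  expect_gt(cor(pe$effect, truth_pe), 0.95)
})

test_that("a logistic thermal preference peaking at zero is recovered", {
  withr::with_seed(102, d <- make_presence_rows(n = 5000))
  fit <- fit_pam(model_spec("presence", "binomial",
                            fixed = smooth_term("sst_optimal")), d)
  expect_lt(abs(effect_argmax(fit, "sst_optimal", n = 400)), 1)
})

test_that("family domains and row minimums are enforced", {
  d <- data.frame(y = rnorm(100), x = rnorm(100))
  expect_error(fit_pam(model_spec("y", "gaussian",
                                  fixed = smooth_term("x")), d[1:20, ]),
               "at least 50")
  d$b <- rep(c(0, 1, 2, 1), 25)
  expect_error(fit_pam(model_spec("b", "binomial",
                                  fixed = smooth_term("x")), d),
               "0/1")
  d$g <- d$y  # has non-positive values
  expect_error(fit_pam(model_spec("g", "gamma_log",
                                  fixed = smooth_term("x")), d),
               "positive")
})

test_that("stepwise selection keeps informative terms and drops noise", {
  withr::with_seed(103, {
    n <- 2000
    d <- data.frame(x_signal = runif(n, -2, 2), x_noise1 = rnorm(n),
                    x_noise2 = rnorm(n), x_noise3 = rnorm(n))
    d$y <- sin(2 * d$x_signal) + rnorm(n, 0, 0.4)
  })
  cands <- list(smooth_term("x_noise1"), smooth_term("x_signal"),
                smooth_term("x_noise2"), smooth_term("x_noise3"))
  sel <- stepwise_select(cands, model_spec("y", "gaussian"), d)
  kept <- vapply(sel$spec$fixed, function(t) t$var, character(1))
  expect_identical(kept, "x_signal")
  expect_true(any(sel$trace$retained))
  # trace records every comparison of every round
  expect_gte(nrow(sel$trace), 4)

  # empty candidate list returns the base spec unchanged
  sel0 <- stepwise_select(list(), model_spec("y", "gaussian"), d)
  expect_length(sel0$spec$fixed, 0)

  # a duplicated term adds no AIC improvement and is dropped
  d$x_dup <- d$x_signal
  sel2 <- stepwise_select(list(smooth_term("x_signal"),
                               smooth_term("x_dup")),
                          model_spec("y", "gaussian"), d)
  kept2 <- vapply(sel2$spec$fixed, function(t) t$var, character(1))
  expect_identical(kept2, "x_signal")
})

test_that("deviance decomposition follows the nested-refit definition", {
  withr::with_seed(104, {
    n <- 600
    id <- factor(sample(letters[1:12], n, TRUE))
    re <- rnorm(12, 0, 1.5)
    d <- data.frame(x = runif(n, -2, 2), animal_id = id)
    d$y <- sin(d$x) + re[as.integer(id)] + rnorm(n, 0, 0.3)
  })
  fit <- fit_pam(model_spec("y", "gaussian", fixed = smooth_term("x"),
                            random = "animal_id"), d)
  dec <- deviance_decomposition(fit)
  expect_gte(dec[["fixed"]], 0)
  expect_gt(dec[["random"]], 0)  # strong random intercepts present
  expect_lte(dec[["fixed"]] + dec[["random"]], 100)
  # the full model explains at least as much as the fixed-only refit
  fixed_only <- fit_pam(model_spec("y", "gaussian",
                                   fixed = smooth_term("x")), d)
  expect_gte(100 * fit$dev_expl, 100 * fixed_only$dev_expl - 1e-6)
  expect_equal(dec[["fixed"]], 100 * fixed_only$dev_expl)

  # no random terms: random share is exactly zero
  dec0 <- deviance_decomposition(fixed_only)
  expect_equal(dec0[["random"]], 0)

  # a response that IS a smooth of x saturates the fixed share
  d$y2 <- sin(d$x)
  sat <- fit_pam(model_spec("y2", "gaussian", fixed = smooth_term("x")), d)
  expect_gt(100 * sat$dev_expl, 99.9)
})

test_that("fits are invariant to row order and calibrated in prevalence", {
  withr::with_seed(105, d <- make_presence_rows(n = 2000))
  fit1 <- fit_pam(model_spec("presence", "binomial",
                             fixed = smooth_term("sst_optimal")), d)
  fit2 <- fit_pam(model_spec("presence", "binomial",
                             fixed = smooth_term("sst_optimal")),
                  d[sample(nrow(d)), ])
  expect_equal(fit1$dev_expl, fit2$dev_expl, tolerance = 1e-8)
  expect_equal(fit1$aic, fit2$aic, tolerance = 1e-6)
  p <- predict(fit1$gam, type = "response")
  expect_true(all(p > 0 & p < 1))
  # IRLS score equation: mean fitted probability matches prevalence
  expect_equal(mean(p), mean(d$presence), tolerance = 1e-6)
})

test_that("class-interaction occurrence model recovers the optimum end-to-end", {
  env <- gradient_env(gradient = 0.5, base = 22, n_days = 160,
                      lat_min = -36, lat_max = -24, lon_min = 150,
                      lon_max = 160, noise_sd = 0.2)
  chl <- flat_env(value = 0.4, n_days = 160, lat_min = -36,
                  lat_max = -24, lon_min = 150, lon_max = 160,
                  variable = "chla")
  oni <- gen_oni_series("2019-01-01", "2019-06-30", seed = 111)
  tr <- gen_tracks(8, c(juvenile_female = 1), env,
                   preference_params(thermal_optimum = 22,
                                     thermal_sd = 0.8, step_scale = 45),
                   n_days = 60, t0 = as.Date("2019-01-15"), seed = 112)
  tr <- annotate_track(tr)
  pss <- lapply(split(tr, tr$animal_id), simulate_pseudo_tracks,
                n_sim = 12, n_keep = 12, seed = 113)
  rows <- build_covariate_table(tr, pss, env, chl, oni)
  rows <- rows[rows$region == "South", ]
  fit <- fit_pam(model_spec("presence", "binomial",
                            fixed = smooth_term("sst_optimal",
                                                by = "class"),
                            random = "animal_id"), rows)
  peak <- effect_argmax(fit, "sst_optimal",
                        level = "juvenile_female", n = 300)
  expect_lt(abs(peak), 1.5)
})

test_that("depth model retains a region-by-season interaction when present", {
  withr::with_seed(121, {
    n <- 1500
    d <- data.frame(
      animal_id = factor(sample(sprintf("A%02d", 1:15), n, TRUE)),
      region = factor(sample(c("North", "South"), n, TRUE)),
      month = sample(1:12, n, TRUE),
      oni = rnorm(n, 0, 0.8),
      year = factor(sample(2017:2019, n, TRUE)))
    d$tagging_region <- d$region
    # deeper dives in the northern summer only
    mu <- exp(3 + 1.0 * (d$region == "North") * sin(2 * pi * d$month / 12))
    d$max_depth_m <- rgamma(n, shape = 6, rate = 6 / mu)
    d$presence <- 1L
    d$usable <- TRUE
  })
  fit <- fit_model3_depth(d, select = TRUE)
  kept <- vapply(fit$spec$fixed, function(t) t$var, character(1))
  expect_true("month" %in% kept)
  expect_s3_class(fit$gam, "gam")
  expect_equal(fit$spec$family, "gamma_log")
})

test_that("classes observed on too few animals are excluded with a warning", {
  withr::with_seed(122, {
    n <- 400
    d <- data.frame(
      animal_id = c(sample(sprintf("F%02d", 1:8), n - 20, TRUE),
                    sample(c("M01", "M02"), 20, TRUE)),
      presence = 1L, usable = TRUE,
      lat = runif(n, -35, -25), sst_optimal = rnorm(n),
      derivative_sst = rnorm(n), derivative_chla = rnorm(n),
      oni = rnorm(n), month = sample(1:12, n, TRUE),
      year = factor(2019), tagging_region = factor("South"))
    d$class <- factor(ifelse(grepl("^F", d$animal_id),
                             "juvenile_female", "adult_male"),
                      levels = predcast:::CLASS_LEVELS)
    d$y <- rnorm(n)
  })
  expect_warning(out <- predcast:::exclude_small_classes(d),
                 "adult_male")
  expect_false("adult_male" %in% out$class)
  expect_equal(nlevels(out$class), 1L)
})

test_that("model summaries serialize with the fixed/random split", {
  withr::with_seed(123, {
    n <- 300
    d <- data.frame(x = runif(n, -2, 2),
                    animal_id = factor(sample(letters[1:8], n, TRUE)))
    d$y <- sin(d$x) + rnorm(n, 0.3)
  })
  fit <- fit_pam(model_spec("y", "gaussian", fixed = smooth_term("x"),
                            random = "animal_id"), d)
  tab <- fit_summary_table(fit)
  expect_setequal(tab$Type, c("Fixed", "Random"))
  expect_true(all(c("edf", "Ref.df", "statistic", "p") %in% names(tab)))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_summary(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$family, "gaussian")
  expect_equal(back$n, n)
  expect_length(back$terms, nrow(tab))
})
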