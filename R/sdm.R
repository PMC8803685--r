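# Class-interaction penalized additive models (GAMM-style).
#
# Smooth terms are penalized regression splines; "random effects" are
# i.i.d.-Gaussian-penalized factor intercepts (the ridge-penalty
# equivalence, bs = "re"), so a single penalized-likelihood fit covers
# both.  Four descriptive models are exposed: latitudinal movement
# (Gaussian), North and South region occurrence against the CRW
# pseudo-absences (binomial), and maximum dive depth (Gamma, log link).

#' Declare a smooth model term
#'
#' @param var covariate name.
#' @param by optional factor name for a by-factor interaction smooth
#'   (one smooth per level); the factor's main effect is added
#'   automatically.
#' @param k basis dimension; interacting smooths are capped at 10 to
#'   avoid overfitting.
#' @param bs basis type (`"tp"` default; use `"cc"` for cyclic
#'   covariates such as month).
#' @return object of class `smooth_term`.
#' @export
smooth_term <- function(var, by = NULL, k = 10, bs = "tp") {
  if (!is.null(by)) {
    stop_if_not(k <= 10, "interacting smooths are capped at k = 10")
  }
  structure(list(var = var, by = by, k = k, bs = bs),
            class = "smooth_term")
}

term_label <- function(st) {
  if (is.null(st$by)) {
    sprintf('s(%s, k = %d, bs = "%s")', st$var, st$k, st$bs)
  } else {
    sprintf('s(%s, by = %s, k = %d, bs = "%s")', st$var, st$by, st$k, st$bs)
  }
}

#' Specify a penalized additive model
#'
#' @param response response column name.
#' @param family `"gaussian"`, `"binomial"`, or `"gamma_log"`.
#' @param fixed list of [smooth_term()]s.
#' @param random character vector of factor columns fitted as
#'   ridge-penalized random intercepts.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, family = c("gaussian", "binomial",
                                            "gamma_log"),
                       fixed = list(), random = character()) {
  family <- match.arg(family)
  if (inherits(fixed, "smooth_term")) fixed <- list(fixed)
  structure(list(response = response, family = family, fixed = fixed,
                 random = random),
            class = "model_spec")
}

spec_family <- function(spec) {
  switch(spec$family,
         gaussian = stats::gaussian(),
         binomial = stats::binomial(),
         gamma_log = stats::Gamma(link = "log"))
}

spec_vars <- function(spec) {
  unique(c(spec$response,
           unlist(lapply(spec$fixed, function(t) c(t$var, t$by))),
           spec$random))
}

spec_formula <- function(spec) {
  by_factors <- unique(unlist(lapply(spec$fixed, function(t) t$by)))
  parts <- c(by_factors,
             vapply(spec$fixed, term_label, character(1)),
             sprintf('s(%s, bs = "re")', spec$random))
  rhs <- if (length(parts)) paste(parts, collapse = " + ") else "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit a penalized additive model with random intercepts
#'
#' Fits `spec` by penalized IRLS (smoothing parameters by GCV), with
#' factor random intercepts realised as ridge-penalized terms. Random
#' terms whose factor has fewer than two levels in the data are dropped
#' with a message (they are unidentifiable). Rows with missing values in
#' any model variable are excluded.
#'
#' @param spec a [model_spec()].
#' @param rows covariate table (data frame).
#' @param min_rows minimum usable rows (default 50).
#' @return object of class `pam_fit`: list with the fitted `mgcv::gam`
#'   object (`$gam`), the fitting data (`$data`), `$spec`, `$aic`,
#'   `$dev_expl` (proportion), and the smooth/parametric summary tables.
#' @export
fit_pam <- function(spec, rows, min_rows = 50) {
  vars <- spec_vars(spec)
  missing_vars <- setdiff(vars, names(rows))
  stop_if_not(length(missing_vars) == 0,
              paste("missing columns:", paste(missing_vars, collapse = ", ")))
  df <- rows[stats::complete.cases(rows[vars]), , drop = FALSE]
  stop_if_not(nrow(df) >= min_rows,
              sprintf("need at least %d usable rows, have %d",
                      min_rows, nrow(df)))
  fac_vars <- unique(c(spec$random,
                       unlist(lapply(spec$fixed, function(t) t$by))))
  for (v in fac_vars) df[[v]] <- droplevels(factor(df[[v]]))
  drop <- spec$random[vapply(spec$random,
                             function(v) nlevels(df[[v]]) < 2, logical(1))]
  if (length(drop)) {
    message("dropping single-level random term(s): ",
            paste(drop, collapse = ", "))
    spec$random <- setdiff(spec$random, drop)
  }
  # a single-level interaction factor degrades to a plain smooth
  spec$fixed <- lapply(spec$fixed, function(t) {
    if (!is.null(t$by) && nlevels(df[[t$by]]) < 2) t$by <- NULL
    t
  })
  y <- df[[spec$response]]
  if (spec$family == "binomial") {
    stop_if_not(all(y %in% c(0, 1)), "binomial response must be 0/1")
  }
  if (spec$family == "gamma_log") {
    stop_if_not(all(y > 0), "Gamma response must be strictly positive")
  }
  fit <- mgcv::gam(spec_formula(spec), data = df, family = spec_family(spec))
  if (fit$rank < length(fit$coefficients)) {
    mm <- stats::model.matrix(fit)
    qr_ <- qr(mm)
    aliased <- colnames(mm)[qr_$pivot[-seq_len(qr_$rank)]]
    terms_ <- unique(sub("\\.?[0-9]*$", "", aliased))
    stop("rank-deficient design; offending term(s): ",
         paste(terms_, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(spec = spec, gam = fit, data = df,
                 aic = stats::AIC(fit),
                 dev_expl = as.numeric(sm$dev.expl),
                 s_table = sm$s.table, p_table = sm$p.table),
            class = "pam_fit")
}

#' @export
print.pam_fit <- function(x, ...) {
  cat(sprintf("<pam_fit %s [%s]>  n = %d, AIC = %.1f, dev.expl = %.1f%%\n",
              x$spec$response, x$spec$family, nrow(x$data), x$aic,
              100 * x$dev_expl))
  if (!is.null(x$s_table)) print(round(x$s_table, 3))
  invisible(x)
}

#' Split deviance explained into fixed and random components
#'
#' The fixed share is the deviance explained by a refit of the model
#' without its random intercepts on the same rows; the random share is
#' the full model's deviance explained minus the fixed share (clamped at
#' zero against numerical slack from independent smoothing-parameter
#' selection). Both are percentages of the null deviance.
#'
#' @param fit a [fit_pam()] result.
#' @return named numeric vector `c(fixed = %, random = %)`.
#' @export
deviance_decomposition <- function(fit) {
  full_pct <- 100 * fit$dev_expl
  if (length(fit$spec$random) == 0) {
    return(c(fixed = full_pct, random = 0))
  }
  fixed_spec <- fit$spec
  fixed_spec$random <- character()
  fixed_fit <- mgcv::gam(spec_formula(fixed_spec), data = fit$data,
                         family = spec_family(fixed_spec))
  fixed_pct <- 100 * as.numeric(summary(fixed_fit)$dev.expl)
  c(fixed = fixed_pct, random = max(0, full_pct - fixed_pct))
}

#' Forward stepwise term selection by AIC weight
#'
#' Starting from `base_spec` (typically intercept plus random effects),
#' candidate terms are added one at a time; at each round the candidate
#' giving the lowest AIC is retained only if it beats the current model
#' by more than `delta_aic` (default 2, i.e. its Akaike weight within
#' the pair exceeds ~0.73). Selection stops when no candidate clears the
#' threshold. Every comparison is recorded in the trace.
#'
#' @param candidate_terms list of [smooth_term()]s.
#' @param base_spec a [model_spec()].
#' @param rows covariate table.
#' @param delta_aic AIC improvement required to retain a term.
#' @param min_rows passed to [fit_pam()].
#' @return list with `spec` (final), `fit` (final [fit_pam()] result)
#'   and `trace` (data frame of every comparison: step, term, current
#'   and candidate AIC, the candidate's Akaike weight within the pair,
#'   and whether it was retained).
#' @export
stepwise_select <- function(candidate_terms, base_spec, rows,
                            delta_aic = 2, min_rows = 50) {
  if (inherits(candidate_terms, "smooth_term")) {
    candidate_terms <- list(candidate_terms)
  }
  current_spec <- base_spec
  current_fit <- fit_pam(current_spec, rows, min_rows)
  remaining <- candidate_terms
  trace <- list()
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    aics <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      try_spec <- current_spec
      try_spec$fixed <- c(try_spec$fixed, remaining[i])
      fits[i] <- list(tryCatch(fit_pam(try_spec, rows, min_rows),
                               error = function(e) NULL))
      if (!is.null(fits[[i]])) aics[i] <- fits[[i]]$aic
    }
    for (i in seq_along(remaining)) {
      d <- current_fit$aic - aics[i]
      w <- exp(-0.5 * pmax(0, -d)) /
        (exp(-0.5 * pmax(0, -d)) + exp(-0.5 * pmax(0, d)))
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, term = term_label(remaining[[i]]),
        aic_current = current_fit$aic, aic_candidate = aics[i],
        delta_aic = d, weight_candidate = w, retained = FALSE)
    }
    if (all(is.na(aics))) break
    best <- which.min(aics)
    if ((current_fit$aic - aics[best]) > delta_aic) {
      trace[[length(trace) - length(remaining) + best]]$retained <- TRUE
      current_spec$fixed <- c(current_spec$fixed, remaining[best])
      current_fit <- fits[[best]]
      remaining <- remaining[-best]
    } else {
      break
    }
  }
  list(spec = current_spec, fit = current_fit,
       trace = do.call(rbind, trace))
}

#' Report-only multicollinearity screen
#'
#' Pairwise Pearson correlations among candidate covariates; pairs with
#' `|r|` at or above the flag threshold are reported but nothing is
#' dropped automatically.
#'
#' @param rows covariate table.
#' @param vars covariate columns to screen.
#' @param flag_threshold absolute correlation that triggers a flag
#'   (default 0.7).
#' @return data frame of flagged pairs (possibly empty) with the full
#'   correlation matrix in attribute `"cor"`.
#' @export
collinearity_screen <- function(rows, vars, flag_threshold = 0.7) {
  cc <- stats::cor(rows[vars], use = "pairwise.complete.obs")
  pairs <- which(abs(cc) >= flag_threshold & upper.tri(cc), arr.ind = TRUE)
  out <- data.frame(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                    r = cc[pairs])
  attr(out, "cor") <- cc
  out
}

# Drop biological classes observed on fewer than `min_animals` animals.
exclude_small_classes <- function(rows, min_animals = 6) {
  n_by_class <- tapply(rows$animal_id, rows$class,
                       function(x) length(unique(x)))
  n_by_class[is.na(n_by_class)] <- 0
  small <- names(n_by_class)[n_by_class > 0 & n_by_class < min_animals]
  if (length(small)) {
    warning("excluding class(es) with fewer than ", min_animals,
            " animals: ", paste(small, collapse = ", "))
    rows <- rows[!(as.character(rows$class) %in% small), , drop = FALSE]
  }
  rows$class <- droplevels(factor(rows$class))
  rows
}

model1_candidates <- function(k = 10) {
  list(smooth_term("sst_optimal", by = "class", k = k),
       smooth_term("month", by = "class", k = min(k, 8), bs = "cc"),
       smooth_term("derivative_sst", by = "class", k = k),
       smooth_term("oni", by = "class", k = k),
       smooth_term("derivative_chla", by = "class", k = k))
}

run_model <- function(spec, candidates, rows, select, delta_aic, min_rows) {
  if (select) {
    sel <- stepwise_select(candidates, spec, rows, delta_aic, min_rows)
    fit <- sel$fit
    fit$selection <- sel$trace
    fit
  } else {
    spec$fixed <- candidates
    fit_pam(spec, rows, min_rows)
  }
}

#' Fit the four descriptive movement models
#'
#' `fit_model1_latitude()` models observed latitude of real daily
#' locations (Gaussian) with class-interacting smooths of the candidate
#' covariates and random intercepts for animal, tagging region and year.
#' `fit_model2a_north()` / `fit_model2b_south()` model presence (real)
#' versus pseudo-absence (simulated) with binomial families within each
#' marine region; the South model omits the tagging-region random effect
#' because animals tagged in the North are not observed in the South.
#' `fit_model3_depth()` models daily maximum dive depth (Gamma, log
#' link) pooled across classes, with region-interacting smooths of the
#' ENSO index and month.
#'
#' Classes observed on fewer than `min_animals` animals are excluded
#' with a warning before fitting the class-interaction models.
#'
#' @param rows covariate table from [build_covariate_table()].
#' @param select run forward stepwise selection (default `TRUE`); when
#'   `FALSE` all candidates enter the model.
#' @param delta_aic stepwise retention threshold, see
#'   [stepwise_select()].
#' @param k basis dimension cap for interacting smooths.
#' @param min_animals class-exclusion threshold (default 6).
#' @param min_rows minimum usable rows.
#' @return a [fit_pam()] result, with the selection trace in
#'   `$selection` when `select = TRUE`.
#' @export
fit_model1_latitude <- function(rows, select = TRUE, delta_aic = 2, k = 10,
                                min_animals = 6, min_rows = 50) {
  d <- rows[rows$presence == 1 & rows$usable, , drop = FALSE]
  d <- exclude_small_classes(d, min_animals)
  spec <- model_spec("lat", "gaussian",
                     random = c("animal_id", "tagging_region", "year"))
  run_model(spec, model1_candidates(k), d, select, delta_aic, min_rows)
}

#' @rdname fit_model1_latitude
#' @export
fit_model2a_north <- function(rows, select = TRUE, delta_aic = 2, k = 10,
                              min_animals = 6, min_rows = 50) {
  d <- rows[rows$region == "North" & rows$usable, , drop = FALSE]
  d <- exclude_small_classes(d, min_animals)
  spec <- model_spec("presence", "binomial",
                     random = c("animal_id", "tagging_region", "year"))
  run_model(spec, model1_candidates(k), d, select, delta_aic, min_rows)
}

#' @rdname fit_model1_latitude
#' @export
fit_model2b_south <- function(rows, select = TRUE, delta_aic = 2, k = 10,
                              min_animals = 6, min_rows = 50) {
  d <- rows[rows$region == "South" & rows$usable, , drop = FALSE]
  d <- exclude_small_classes(d, min_animals)
  spec <- model_spec("presence", "binomial",
                     random = c("animal_id", "year"))
  run_model(spec, model1_candidates(k), d, select, delta_aic, min_rows)
}

#' @rdname fit_model1_latitude
#' @export
fit_model3_depth <- function(rows, select = TRUE, delta_aic = 2, k = 10,
                             min_rows = 50) {
  d <- rows[rows$presence == 1 & rows$usable & !is.na(rows$max_depth_m), ,
            drop = FALSE]
  candidates <- list(smooth_term("oni", by = "region", k = k),
                     smooth_term("month", by = "region", k = min(k, 8),
                                 bs = "cc"))
  spec <- model_spec("max_depth_m", "gamma_log",
                     random = c("animal_id", "tagging_region", "year"))
  run_model(spec, candidates, d, select, delta_aic, min_rows)
}

#' Partial effect of a smooth term
#'
#' Evaluates the fitted smooth of `var` (for one level of its `by`
#' factor, where applicable) over a regular grid of the covariate, with
#' all other covariates held at their medians (numeric) or modal level
#' (factors). Random-effect terms do not contribute.
#'
#' @param fit a [fit_pam()] result.
#' @param var covariate name.
#' @param level `by`-factor level (default: first level present).
#' @param n grid size.
#' @return data frame with columns `x` and `effect`.
#' @export
partial_effect <- function(fit, var, level = NULL, n = 200) {
  df <- fit$data
  grid <- seq(min(df[[var]], na.rm = TRUE), max(df[[var]], na.rm = TRUE),
              length.out = n)
  newdata <- df[rep(1L, n), , drop = FALSE]
  for (v in names(newdata)) {
    if (is.numeric(newdata[[v]])) {
      newdata[[v]] <- stats::median(df[[v]], na.rm = TRUE)
    } else if (is.factor(newdata[[v]])) {
      newdata[[v]] <- factor(names(which.max(table(df[[v]]))),
                             levels = levels(df[[v]]))
    }
  }
  newdata[[var]] <- grid
  by_vars <- unique(unlist(lapply(fit$spec$fixed, function(t) {
    if (identical(t$var, var)) t$by else NULL
  })))
  if (length(by_vars)) {
    level <- level %||% levels(df[[by_vars[1]]])[1]
    newdata[[by_vars[1]]] <- factor(level, levels = levels(df[[by_vars[1]]]))
  }
  terms_mat <- stats::predict(fit$gam, newdata = newdata, type = "terms")
  cols <- grep(sprintf("^s\\(%s\\)(:|$)", var), colnames(terms_mat))
  stop_if_not(length(cols) > 0,
              sprintf("no smooth of '%s' in the model", var))
  data.frame(x = grid, effect = rowSums(terms_mat[, cols, drop = FALSE]))
}

#' Argmax of a fitted partial effect
#'
#' @inheritParams partial_effect
#' @return covariate value at which the partial effect is largest.
#' @export
effect_argmax <- function(fit, var, level = NULL, n = 200) {
  pe <- partial_effect(fit, var, level, n)
  pe$x[which.max(pe$effect)]
}

#' Summary table in the descriptive-model layout
#'
#' One row per fixed smooth and per random intercept with edf, reference
#' df, test statistic and p-value, plus the fixed/random deviance
#' decomposition.
#'
#' @param fit a [fit_pam()] result.
#' @return data frame; deviance shares are in attribute `"dev_expl"`.
#' @export
fit_summary_table <- function(fit) {
  st <- fit$s_table
  labels <- rownames(st)
  re_labels <- sprintf("s(%s)", fit$spec$random)
  type <- ifelse(labels %in% re_labels, "Random", "Fixed")
  out <- data.frame(Type = type, Variable = labels,
                    edf = st[, "edf"], Ref.df = st[, "Ref.df"],
                    statistic = st[, 3], p = st[, 4], row.names = NULL)
  out <- out[order(out$Type), , drop = FALSE]
  attr(out, "dev_expl") <- deviance_decomposition(fit)
  out
}

#' Serialize a fitted model summary to JSON
#'
#' @param fit a [fit_pam()] result.
#' @param path output file.
#' @export
write_fit_summary <- function(fit, path) {
  tab <- fit_summary_table(fit)
  dev <- attr(tab, "dev_expl")
  obj <- list(response = fit$spec$response, family = fit$spec$family,
              n = nrow(fit$data), aic = fit$aic,
              dev_expl_fixed_pct = unname(dev["fixed"]),
              dev_expl_random_pct = unname(dev["random"]),
              terms = tab)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
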