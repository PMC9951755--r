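# Prediction-bias decomposition for a UN equation: residuals regressed on
# mean-centered predictions with a diet-type interaction in a weighted
# random-intercept model. The intercept is the mean bias, the slope the
# linear bias; RMSEP/RPE are computed per diet on raw residuals.

#' Observed-minus-predicted UN residuals
#'
#' @param table a \code{study_table} (or compatible data frame).
#' @param eq equation id or \code{coefficient_set}.
#' @return Numeric vector \code{un_gd - predict_un(eq, table)}: an
#'   over-prediction gives a negative residual.
#' @export
un_residuals <- function(table, eq) {
  table$un_gd - predict_un(eq, table)
}

#' Center values at their grand mean
#'
#' The grand mean is taken over the full evaluation set (both diets
#' pooled), so per-diet intercepts of the bias regression are comparable.
#'
#' @param values numeric vector.
#' @return \code{values - mean(values)}; the output has mean zero.
#' @export
mean_center <- function(values) {
  if (length(values) == 0L) stop("cannot center an empty vector", call. = FALSE)
  values - mean(values)
}

#' Mean and linear prediction bias of a UN equation
#'
#' Implements the evaluation regression: residuals (observed minus
#' predicted UN) are modeled on the grand-mean-centered predictions with a
#' diet-type interaction, a random study intercept, and inverse-SEm-squared
#' weights. Mean centering makes each diet's intercept the mean prediction
#' bias and its slope the linear prediction bias. RMSEP and RPE are
#' computed per diet subset on the raw (unweighted) residuals, alongside
#' the weighted regression.
#'
#' @param table a \code{study_table} containing both diet types (a single
#'   diet degrades to a no-interaction model with a warning) and, unless
#'   \code{weighted = FALSE}, a positive \code{un_sem} on every row.
#' @param eq equation id or \code{coefficient_set}.
#' @param weighted use SEm weighting (default) or equal weights.
#' @return An object of class \code{"bias_report"}: \code{equation};
#'   \code{per_diet}, a data frame with one row per diet holding
#'   \code{mean_bias} (signed mean residual scale, g/d; negative =
#'   over-prediction), \code{mean_bias_se}, \code{mean_bias_p},
#'   \code{linear_bias}, \code{linear_bias_se}, \code{linear_bias_p},
#'   \code{rmsep}, \code{rpe}; \code{interaction_p_mean} and
#'   \code{interaction_p_linear}, the p-values for a diet difference in
#'   intercept and slope; and the underlying \code{fit}.
#' @export
assess_bias <- function(table, eq, weighted = TRUE) {
  eq_id <- if (inherits(eq, "coefficient_set")) eq$id else eq
  pred <- predict_un(eq, table)
  resid <- table$un_gd - pred
  diets <- levels(droplevels(table$diet))

  d <- data.frame(study_id = table$study_id,
                  diet = droplevels(table$diet),
                  resid = resid,
                  cpred = mean_center(pred))
  w <- if (weighted) {
    validate_study_table(as.data.frame(table), require_sem = TRUE)
    build_weights(table$un_sem)
  } else {
    rep(1, nrow(table))
  }

  per_diet_stats <- function(dd) {
    r <- resid[table$diet == dd]
    obs <- table$un_gd[table$diet == dd]
    c(rmsep = sqrt(mean(r^2)),
      rpe = 100 * sqrt(mean(r^2)) / mean(obs))
  }
  rr <- t(vapply(diets, per_diet_stats, numeric(2)))

  if (all(abs(resid) < 1e-12)) {
    # perfect predictions: the regression is degenerate; everything is zero
    per_diet <- data.frame(diet = diets,
                           mean_bias = 0, mean_bias_se = NA_real_,
                           mean_bias_p = NA_real_,
                           linear_bias = 0, linear_bias_se = NA_real_,
                           linear_bias_p = NA_real_,
                           rmsep = rr[, "rmsep"], rpe = rr[, "rpe"],
                           stringsAsFactors = FALSE)
    return(structure(list(equation = eq_id, per_diet = per_diet,
                          interaction_p_mean = NA_real_,
                          interaction_p_linear = NA_real_,
                          fit = NULL, weighted = weighted),
                     class = "bias_report"))
  }

  if (length(diets) >= 2L) {
    # cell-means parameterization: one intercept and one slope per diet
    fit_cm <- fit_wlmm(resid ~ 0 + diet + diet:cpred, d, weights = w)
    # treatment parameterization: diet main effect / interaction p-values
    fit_tr <- fit_wlmm(resid ~ diet * cpred, d, weights = w)
    wt <- wald_tests(fit_cm)
    pick <- function(term) wt[wt$term == term, ]
    per_diet <- do.call(rbind, lapply(diets, function(dd) {
      mb <- pick(paste0("diet", dd))
      lb <- pick(paste0("diet", dd, ":cpred"))
      data.frame(diet = dd,
                 mean_bias = mb$estimate, mean_bias_se = mb$se,
                 mean_bias_p = mb$p,
                 linear_bias = lb$estimate, linear_bias_se = lb$se,
                 linear_bias_p = lb$p,
                 rmsep = rr[dd, "rmsep"], rpe = rr[dd, "rpe"],
                 stringsAsFactors = FALSE)
    }))
    wtr <- wald_tests(fit_tr)
    other <- diets[2L]
    interaction_p_mean <- wtr$p[wtr$term == paste0("diet", other)]
    interaction_p_linear <- wtr$p[wtr$term == paste0("diet", other, ":cpred")]
    fit <- fit_cm
  } else {
    warning("single diet type in table: fitting a no-interaction bias model",
            call. = FALSE)
    fit <- fit_wlmm(resid ~ cpred, d, weights = w)
    wt <- wald_tests(fit)
    per_diet <- data.frame(diet = diets,
                           mean_bias = wt$estimate[wt$term == "(Intercept)"],
                           mean_bias_se = wt$se[wt$term == "(Intercept)"],
                           mean_bias_p = wt$p[wt$term == "(Intercept)"],
                           linear_bias = wt$estimate[wt$term == "cpred"],
                           linear_bias_se = wt$se[wt$term == "cpred"],
                           linear_bias_p = wt$p[wt$term == "cpred"],
                           rmsep = rr[, "rmsep"], rpe = rr[, "rpe"],
                           stringsAsFactors = FALSE)
    interaction_p_mean <- NA_real_
    interaction_p_linear <- NA_real_
  }
  rownames(per_diet) <- NULL
  structure(list(equation = eq_id, per_diet = per_diet,
                 interaction_p_mean = interaction_p_mean,
                 interaction_p_linear = interaction_p_linear,
                 fit = fit, weighted = weighted),
            class = "bias_report")
}

#' Translate a signed mean bias into over/under-prediction language
#'
#' The report stores the signed mean residual (observed minus predicted);
#' a negative value means the equation over-predicts on average.
#'
#' @param mean_bias signed mean residual, g/d.
#' @return A sentence fragment, e.g. \code{"over predicted by 31.4 g/d"}.
#' @export
describe_mean_bias <- function(mean_bias) {
  stopifnot(is.numeric(mean_bias), length(mean_bias) == 1L)
  if (mean_bias < 0) {
    sprintf("over predicted by %.1f g/d", abs(mean_bias))
  } else if (mean_bias > 0) {
    sprintf("under predicted by %.1f g/d", mean_bias)
  } else {
    "unbiased on average"
  }
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("Prediction-bias report for %s (%s weighting)\n", x$equation,
              if (x$weighted) "SEm" else "equal"))
  pd <- x$per_diet
  for (i in seq_len(nrow(pd))) {
    cat(sprintf(
      "  %-8s mean bias %8.2f (SE %s, p %s) | linear bias %7.3f (SE %s, p %s) | RMSEP %6.1f | RPE %5.1f%%\n",
      pd$diet[i], pd$mean_bias[i], fmt_or_na(pd$mean_bias_se[i]),
      fmt_or_na(pd$mean_bias_p[i], 3), pd$linear_bias[i],
      fmt_or_na(pd$linear_bias_se[i]), fmt_or_na(pd$linear_bias_p[i], 3),
      pd$rmsep[i], pd$rpe[i]))
  }
  cat(sprintf("  diet difference: intercept p = %s, slope p = %s\n",
              fmt_or_na(x$interaction_p_mean, 3),
              fmt_or_na(x$interaction_p_linear, 3)))
  invisible(x)
}

fmt_or_na <- function(x, digits = 2) {
  if (is.na(x)) "NA" else formatC(x, digits = digits, format = "g")
}

#' Regress equation residuals on a single covariate
#'
#' Weighted random-intercept regression of observed-minus-predicted UN on
#' one covariate. A significant slope indicates variation the original
#' equation does not explain but the covariate could.
#'
#' @param table a \code{study_table} with \code{un_sem} unless
#'   \code{weighted = FALSE}.
#' @param eq equation id or \code{coefficient_set}.
#' @param covariate covariate column name (\code{"mun_mgdl"},
#'   \code{"cp_pct"}, \code{"dmi_kg"}, \code{"bw_kg"}, ...).
#' @param weighted use SEm weighting (default).
#' @return One-row data frame: \code{equation}, \code{covariate},
#'   \code{slope}, \code{slope_se}, \code{slope_p}, \code{intercept},
#'   \code{intercept_se}, \code{intercept_p}.
#' @export
residual_covariate_regression <- function(table, eq, covariate,
                                          weighted = TRUE) {
  eq_id <- if (inherits(eq, "coefficient_set")) eq$id else eq
  if (!covariate %in% names(table)) {
    stop("covariate column not found: ", covariate, call. = FALSE)
  }
  if (anyNA(table[[covariate]])) {
    stop("covariate '", covariate, "' has missing values", call. = FALSE)
  }
  d <- data.frame(study_id = table$study_id,
                  resid = un_residuals(table, eq),
                  x = table[[covariate]])
  w <- if (weighted) {
    validate_study_table(as.data.frame(table), require_sem = TRUE)
    build_weights(table$un_sem)
  } else {
    rep(1, nrow(table))
  }
  fit <- fit_wlmm(resid ~ x, d, weights = w)
  wt <- wald_tests(fit)
  data.frame(equation = eq_id, covariate = covariate,
             slope = wt$estimate[wt$term == "x"],
             slope_se = wt$se[wt$term == "x"],
             slope_p = wt$p[wt$term == "x"],
             intercept = wt$estimate[wt$term == "(Intercept)"],
             intercept_se = wt$se[wt$term == "(Intercept)"],
             intercept_p = wt$p[wt$term == "(Intercept)"],
             stringsAsFactors = FALSE)
}
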