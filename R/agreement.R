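# Agreement between observed and predicted UN on the test set: Pearson r,
# Lin's concordance with its location/scale decomposition, RMSEP, and
# relative prediction error.

#' Root mean square error of prediction
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return \code{sqrt(mean((observed - predicted)^2))}, in the response
#'   units (g UN/d).
#' @export
rmsep <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0L)
  sqrt(mean((observed - predicted)^2))
}

#' Relative prediction error
#'
#' RMSEP expressed as a percentage of the observed mean.
#'
#' @param rmsep_value RMSEP, g/d.
#' @param mean_observed observed mean UN, g/d (nonzero).
#' @return \code{100 * rmsep_value / mean_observed}.
#' @export
relative_prediction_error <- function(rmsep_value, mean_observed) {
  if (any(!is.finite(mean_observed) | mean_observed == 0)) {
    stop("mean_observed must be finite and nonzero", call. = FALSE)
  }
  100 * rmsep_value / mean_observed
}

#' Bias correction factor from location and scale shifts
#'
#' \code{Cb = 2 / (v + 1/v + u^2)}, where u is the location shift and v
#' the scale shift. Cb is 1 exactly when u = 0 and v = 1 and decreases as
#' the means or SDs of the two series diverge.
#'
#' @param u location shift.
#' @param v scale shift (> 0).
#' @return Cb in (0, 1].
#' @export
bias_correction_factor <- function(u, v) {
  if (any(!is.finite(v) | v <= 0)) stop("v must be > 0", call. = FALSE)
  2 / (v + 1 / v + u^2)
}

#' Lin's concordance correlation between observed and predicted UN
#'
#' Computes Pearson's r, the location shift \code{u = (mean_pred -
#' mean_obs) / sqrt(sd_pred * sd_obs)}, the scale shift \code{v = sd_pred
#' / sd_obs}, the bias correction factor \code{Cb = 2/(v + 1/v + u^2)},
#' the concordance \code{CCC = r * Cb}, RMSEP and RPE. With
#' \code{moments = "population"} (the default) the SDs inside u and v use
#' the n denominator, which preserves the covariance-form identity
#' \code{CCC = 2 cov(o, p) / (var_o + var_p + (mean_o - mean_p)^2)}
#' exactly; \code{"sample"} uses the n - 1 denominator (v and r are
#' unaffected, u changes by the factor sqrt((n-1)/n)).
#'
#' @param observed,predicted numeric vectors, equal length >= 3, neither
#'   constant.
#' @param moments moment convention for the u/v components.
#' @return An object of class \code{"agreement_report"}: \code{r},
#'   \code{u}, \code{v}, \code{cb}, \code{ccc}, \code{rmsep}, \code{rpe},
#'   \code{n}, \code{moments}.
#' @export
lin_ccc <- function(observed, predicted,
                    moments = c("population", "sample")) {
  moments <- match.arg(moments)
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values in observed or predicted", call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  denom_adj <- if (moments == "population") sqrt((n - 1) / n) else 1
  so <- stats::sd(observed) * denom_adj
  sp <- stats::sd(predicted) * denom_adj
  r <- stats::cor(observed, predicted)
  u <- (mean(predicted) - mean(observed)) / sqrt(sp * so)
  v <- sp / so
  cb <- bias_correction_factor(u, v)
  structure(list(r = r, u = u, v = v, cb = cb, ccc = r * cb,
                 rmsep = rmsep(observed, predicted),
                 rpe = relative_prediction_error(
                   rmsep(observed, predicted), mean(observed)),
                 n = n, moments = moments),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Agreement (n = %d): r %.2f | u %.2f | v %.2f | Cb %.2f | CCC %.2f | RMSEP %.1f g/d | RPE %.1f%%\n",
    x$n, x$r, x$u, x$v, x$cb, x$ccc, x$rmsep, x$rpe))
  invisible(x)
}

#' Descriptive statistics of a UN series
#'
#' @param values numeric vector (g/d).
#' @return One-row data frame: \code{mean}, \code{sd} (sample, n - 1
#'   denominator), \code{cv_pct} (100 * sd/mean), \code{max}, \code{min},
#'   \code{n}.
#' @export
descriptive_stats <- function(values) {
  stopifnot(length(values) > 0L, !anyNA(values))
  s <- if (length(values) > 1L) stats::sd(values) else 0
  m <- mean(values)
  data.frame(mean = m, sd = s, cv_pct = 100 * s / m,
             max = max(values), min = min(values), n = length(values))
}

#' Evaluate prediction equations on a held-out test set
#'
#' One agreement row per equation (observed vs predicted UN) plus
#' descriptive statistics of the observed series and each predicted
#' series.
#'
#' @param test a \code{study_table} (the held-out studies).
#' @param eqs equation ids and/or \code{coefficient_set} objects.
#' @param moments passed to \code{\link{lin_ccc}}.
#' @return A list with \code{agreement} (data frame: \code{equation},
#'   \code{r}, \code{u}, \code{v}, \code{cb}, \code{ccc}, \code{rmsep},
#'   \code{rpe}, \code{n}) and \code{descriptives} (data frame with a
#'   \code{series} column: \code{"observed"} or the equation id).
#' @export
evaluate_on_test <- function(test, eqs = c("EQ4", "EQ5", "EQ6", "EQ7"),
                             moments = "population") {
  if (!is.list(eqs)) eqs <- as.list(eqs)
  obs <- test$un_gd
  desc <- cbind(series = "observed", descriptive_stats(obs))
  rows <- list()
  for (eq in eqs) {
    cs <- if (inherits(eq, "coefficient_set")) eq else equation_coefficients(eq)
    pred <- predict_un(cs, test)
    a <- lin_ccc(obs, pred, moments = moments)
    rows[[cs$id]] <- data.frame(equation = cs$id, r = a$r, u = a$u, v = a$v,
                                cb = a$cb, ccc = a$ccc, rmsep = a$rmsep,
                                rpe = a$rpe, n = a$n,
                                stringsAsFactors = FALSE)
    desc <- rbind(desc, cbind(series = cs$id, descriptive_stats(pred)))
  }
  rownames(desc) <- NULL
  list(agreement = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       descriptives = desc)
}

#' Observed-vs-predicted scatter with the identity line
#'
#' Convenience base-graphics plot for eyeballing agreement; one panel per
#' equation.
#'
#' @param test a \code{study_table}.
#' @param eqs equation ids and/or \code{coefficient_set} objects.
#' @return Invisibly, the list of predicted vectors.
#' @export
plot_observed_vs_predicted <- function(test, eqs = c("EQ4", "EQ5", "EQ6",
                                                     "EQ7")) {
  if (!is.list(eqs)) eqs <- as.list(eqs)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(eqs)))
  on.exit(graphics::par(old))
  preds <- list()
  for (eq in eqs) {
    cs <- if (inherits(eq, "coefficient_set")) eq else equation_coefficients(eq)
    pred <- predict_un(cs, test)
    preds[[cs$id]] <- pred
    rng <- range(test$un_gd, pred)
    plot(pred, test$un_gd, xlim = rng, ylim = rng,
         xlab = "Predicted UN, g/d", ylab = "Observed UN, g/d",
         main = cs$id, pch = 19,
         col = c(TMR = "black", PASTURE = "forestgreen")[as.character(test$diet)])
    graphics::abline(0, 1, lty = 2)
  }
  invisible(preds)
}
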