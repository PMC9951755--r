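# Weighted linear mixed-model engine: a single random intercept per study,
# per-record weights on the residual variance, REML estimation by profiling
# the variance ratio lambda = var_study / var_resid.
#
# Model: y = X beta + u[study] + e,  u ~ N(0, var_study),
#        Var(e_i) = var_resid / w_i.
# The marginal covariance is block diagonal by study, and each block
# inverts in closed form (rank-one update of a diagonal), so every
# criterion evaluation is O(n).

#' Inverse-squared-SEm weights, centered at mean 1
#'
#' The weight of a treatment mean is the inverse of its squared SEm,
#' normalized by the mean of those inverses: \code{w_i = (1/sem_i^2) /
#' mean_j(1/sem_j^2)}. Centering the weights around 1 keeps variance and
#' covariance components on the scale of the response. If every SEm is
#' absent (\code{NULL} or all \code{NA}), all weights are 1 (equal
#' weighting); a mix of present and absent SEm is an error rather than a
#' silent partial weighting.
#'
#' @param sem per-record standard errors of the treatment means (all
#'   positive), or \code{NULL}/all-\code{NA} for equal weights.
#' @param n number of records, used only when \code{sem} is \code{NULL}.
#' @return Numeric weight vector with mean exactly 1.
#' @export
build_weights <- function(sem, n = length(sem)) {
  if (is.null(sem) || (length(sem) > 0L && all(is.na(sem)))) {
    return(rep(1, n))
  }
  if (anyNA(sem)) {
    stop("SEm present for some records but absent for others; ",
         "refusing partial weighting", call. = FALSE)
  }
  if (any(!is.finite(sem) | sem <= 0)) {
    stop("all SEm values must be finite and > 0", call. = FALSE)
  }
  w <- 1 / sem^2
  w / mean(w)
}

# Solve V_lambda^{-1} %*% A groupwise via the rank-one (Woodbury) identity:
# V_g = diag(1/w_g) + lambda * 1 1', so
# V_g^{-1} = diag(w_g) - lambda * w_g w_g' / (1 + lambda * sum(w_g)).
vinv_mult <- function(A, w, group, lambda, group_wsum) {
  A <- as.matrix(A)
  WA <- A * w
  if (lambda == 0) return(WA)
  G <- rowsum(WA, group)                       # per-group colsums of w*A
  shrink <- lambda / (1 + lambda * group_wsum) # per group
  WA - (w * shrink[group]) * G[group, , drop = FALSE]
}

#' Fit a weighted linear mixed model with one random study intercept
#'
#' REML estimation by profiling: for each candidate variance ratio
#' \code{lambda = var_study / var_resid}, fixed effects come from
#' generalized least squares and \code{var_resid} from the profiled REML
#' criterion; \code{lambda} is then found by deterministic bounded scalar
#' search on \code{[0, 1e6]} (log-scale bracketing plus golden-section
#' refinement, tolerance 1e-10). The fit is fully deterministic.
#'
#' @param formula fixed-effects formula, e.g. \code{un_gd ~ mun_mgdl * diet}.
#' @param data data frame holding the response, covariates and the grouping
#'   column.
#' @param group name of the grouping (study identifier) column.
#' @param weights per-record weights (see \code{\link{build_weights}});
#'   \code{NULL} for equal weights. Weights scale the residual precision:
#'   \code{Var(e_i) = var_resid / w_i}.
#' @param fix_lambda fix the variance ratio instead of estimating it
#'   (\code{0} collapses the model to weighted least squares); \code{NULL}
#'   to estimate.
#' @return An object of class \code{"wlmm_fit"} with elements
#'   \code{coefficients}, \code{coef_se}, \code{p_values} (two-sided t,
#'   between-within denominator df \code{n - rank(X) - n_studies + 1}),
#'   \code{var_study}, \code{var_resid}, \code{rsd},
#'   \code{var_partition_study_pct}, \code{var_partition_resid_pct},
#'   \code{loglik_reml}, \code{lambda}, \code{n_obs}, \code{n_studies},
#'   \code{df_residual}, \code{fitted}, \code{residuals}.
#' @export
fit_wlmm <- function(formula, data, group = "study_id", weights = NULL,
                     fix_lambda = NULL) {
  stopifnot(is.data.frame(data))
  if (!group %in% names(data)) {
    stop("grouping column not found: ", group, call. = FALSE)
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights) | weights <= 0)) {
    stop("weights must be positive, finite, and one per record",
         call. = FALSE)
  }
  g <- factor(data[[group]])
  q <- nlevels(g)
  p <- ncol(X)

  qr_x <- qr(X)
  if (qr_x$rank < p) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  gw <- as.numeric(rowsum(weights, g)[levels(g), 1L])
  sum_log_w <- sum(log(weights))

  profile_at <- function(lambda) {
    VinvX <- vinv_mult(X, weights, g, lambda, gw)
    Vinvy <- vinv_mult(y, weights, g, lambda, gw)
    C <- crossprod(X, VinvX)
    beta <- solve(C, crossprod(X, Vinvy))
    r <- y - drop(X %*% beta)
    qform <- sum(r * drop(vinv_mult(r, weights, g, lambda, gw)))
    sigma2 <- max(qform / (n - p), .Machine$double.xmin)
    logdetV <- -sum_log_w + sum(log1p(lambda * gw))
    logdetC <- determinant(C, logarithm = TRUE)$modulus[1L]
    crit <- (n - p) * log(sigma2) + logdetV + logdetC
    list(lambda = lambda, beta = drop(beta), sigma2 = sigma2, C = C,
         crit = crit, logdetV = logdetV, logdetC = logdetC)
  }

  singleton_only <- all(tabulate(g) == 1L)
  if (!is.null(fix_lambda)) {
    stopifnot(is.numeric(fix_lambda), fix_lambda >= 0)
    lambda_hat <- fix_lambda
  } else if (q < 2L || singleton_only) {
    if (singleton_only && q >= 2L) {
      warning("one record per study: var_study is confounded with the ",
              "residual; reporting var_study = 0", call. = FALSE)
    }
    lambda_hat <- 0
  } else {
    # log-spaced bracket over [1e-8, 1e6], then golden-section refinement;
    # the lambda = 0 boundary is always compared against the interior
    # optimum.
    grid <- exp(seq(log(1e-8), log(1e6), length.out = 61L))
    crit_grid <- vapply(grid, function(l) profile_at(l)$crit, numeric(1))
    i <- which.min(crit_grid)
    lo <- if (i == 1L) 0 else grid[i - 1L]
    hi <- if (i == length(grid)) grid[length(grid)] else grid[i + 1L]
    opt <- stats::optimize(function(l) profile_at(l)$crit,
                           interval = c(lo, hi), tol = 1e-10)
    lambda_hat <- if (profile_at(0)$crit <= opt$objective) 0 else opt$minimum
  }

  fit <- profile_at(lambda_hat)
  beta <- fit$beta
  names(beta) <- colnames(X)
  sigma2 <- fit$sigma2
  vcov_beta <- sigma2 * solve(fit$C)
  se <- sqrt(diag(vcov_beta))
  names(se) <- colnames(X)

  df_bw <- max(n - p - q + 1L, 1L)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df_bw, lower.tail = FALSE)

  var_resid <- sigma2
  var_study <- lambda_hat * sigma2
  loglik <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) +
                    fit$logdetV + fit$logdetC + (n - p))

  structure(list(
    coefficients = beta,
    coef_se = se,
    vcov = vcov_beta,
    t_values = tval,
    p_values = pval,
    df_denominator = df_bw,
    var_study = var_study,
    var_resid = var_resid,
    rsd = sqrt(var_resid),
    var_partition_study_pct = 100 * var_study / (var_study + var_resid),
    var_partition_resid_pct = 100 * var_resid / (var_study + var_resid),
    loglik_reml = loglik,
    lambda = lambda_hat,
    n_obs = n,
    n_studies = q,
    rank = p,
    df_residual = n - p,
    fitted = drop(X %*% beta),
    residuals = y - drop(X %*% beta),
    formula = formula,
    group = group,
    weights = weights
  ), class = "wlmm_fit")
}

#' @export
coef.wlmm_fit <- function(object, ...) object$coefficients

#' @export
print.wlmm_fit <- function(x, digits = 4, ...) {
  cat("Weighted mixed model (REML), random intercept per", x$group, "\n")
  cat(deparse(x$formula), "\n")
  tab <- wald_tests(x)
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "estimate", "se", "p")], row.names = FALSE)
  cat(sprintf("RSD %.4g | variance: study %.1f%%, residual %.1f%% | n = %d obs, %d studies\n",
              x$rsd, x$var_partition_study_pct, x$var_partition_resid_pct,
              x$n_obs, x$n_studies))
  invisible(x)
}

#' Wald t tests for the fixed effects of a fitted model
#'
#' Two-sided p-values from t = estimate/SE on the between-within
#' denominator degrees of freedom \code{n_obs - rank(X) - n_studies + 1}.
#'
#' @param fit a \code{wlmm_fit}.
#' @return Data frame with \code{term}, \code{estimate}, \code{se},
#'   \code{df}, \code{t}, \code{p}.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "wlmm_fit"))
  if (any(!is.finite(fit$coef_se) | fit$coef_se == 0)) {
    stop("zero or non-finite coefficient standard error", call. = FALSE)
  }
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$coef_se),
             df = fit$df_denominator,
             t = unname(fit$t_values),
             p = unname(fit$p_values),
             stringsAsFactors = FALSE)
}

#' Variance partition between the study effect and the residual
#'
#' @param fit a \code{wlmm_fit}.
#' @return Named vector \code{c(study_pct, resid_pct)}; the two always sum
#'   to 100.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "wlmm_fit"))
  tot <- fit$var_study + fit$var_resid
  if (tot <= 0) stop("both variance components are zero", call. = FALSE)
  c(study_pct = 100 * fit$var_study / tot,
    resid_pct = 100 * fit$var_resid / tot)
}

# Machine-readable fit summary mirroring the developed-equation report
# layout: coefficient (SE), RSD, variance partition.
#' Serializable summary of a mixed-model fit
#'
#' @param fit a \code{wlmm_fit}.
#' @return A plain list suitable for JSON serialization.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "wlmm_fit"))
  list(
    formula = deparse(fit$formula),
    coefficients = as.list(fit$coefficients),
    coef_se = as.list(fit$coef_se),
    p_values = as.list(fit$p_values),
    rsd = fit$rsd,
    var_study = fit$var_study,
    var_resid = fit$var_resid,
    var_partition_study_pct = fit$var_partition_study_pct,
    var_partition_resid_pct = fit$var_partition_resid_pct,
    loglik_reml = fit$loglik_reml,
    n_obs = fit$n_obs,
    n_studies = fit$n_studies
  )
}
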