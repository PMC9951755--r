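# Synthetic treatment-mean tables with the statistical structure the
# analysis assumes: two diet strata with realistic covariate profiles,
# study-level random intercepts, residual noise, and heterogeneous SEm
# values that make the inverse-SEm^2 weighting non-trivial.

.default_profiles <- function() {
  # per-diet covariate means/SDs typical of training data in this
  # literature: TMR herds are heavier, eat more, and have lower MUN and CP
  # than fresh-forage herds
  list(
    TMR = list(mean = c(mun_mgdl = 13.2, bw_kg = 647.5, dmi_kg = 22.1,
                        cp_pct = 16.7),
               sd = c(mun_mgdl = 3.17, bw_kg = 64.74, dmi_kg = 2.65,
                      cp_pct = 1.85)),
    PASTURE = list(mean = c(mun_mgdl = 18.5, bw_kg = 508.6, dmi_kg = 17.0,
                            cp_pct = 19.5),
                   sd = c(mun_mgdl = 2.46, bw_kg = 63.60, dmi_kg = 3.25,
                          cp_pct = 3.40))
  )
}

.default_correlations <- function() {
  # fixture conventions, not literature estimates: heavier cows eat more
  # (BW~DMI +0.6), higher-protein diets raise MUN (MUN~CP +0.5)
  vars <- c("mun_mgdl", "bw_kg", "dmi_kg", "cp_pct")
  R <- diag(4)
  dimnames(R) <- list(vars, vars)
  R["bw_kg", "dmi_kg"] <- R["dmi_kg", "bw_kg"] <- 0.6
  R["mun_mgdl", "cp_pct"] <- R["cp_pct", "mun_mgdl"] <- 0.5
  R
}

.default_truth <- function() {
  # generating equation: the per-BW MUN + CP form with its published
  # coefficients; variance components back-derived from that model's
  # reported residual SD (0.019 on the UN/BW scale) and 82.9/17.1
  # study/residual variance split
  var_resid <- 0.019^2
  list(equation = equation_coefficients("EQ7"),
       var_study = var_resid * 82.9 / 17.1,
       var_resid = var_resid,
       diet_offsets = NULL)
}

#' Configuration for the synthetic treatment-mean generator
#'
#' Defaults emulate the training conditions of the meta-regression: 38 TMR
#' and 7 pasture studies, 2-5 treatment means each (about 150 means
#' total), per-diet covariate profiles, within-study correlation between
#' covariates, a generating equation with study-level and residual noise,
#' and gamma-distributed SEm values.
#'
#' @param seed integer seed; the generator is deterministic given it.
#' @param n_studies named vector, studies per diet type.
#' @param means_per_study inclusive integer range of treatment means drawn
#'   per study.
#' @param covariate_profiles per-diet list with \code{mean} and \code{sd}
#'   vectors for \code{mun_mgdl}, \code{bw_kg}, \code{dmi_kg},
#'   \code{cp_pct}.
#' @param covariate_correlations within-study correlation matrix of the
#'   four covariates (must be positive semi-definite).
#' @param within_split fraction of covariate variance placed within study
#'   (the rest separates study means); treatment means within a study
#'   share animals and diets, so most variance is between studies.
#' @param truth list: \code{equation} (a \code{coefficient_set} evaluated
#'   on the response scale), \code{var_study}, \code{var_resid} (response
#'   scale), optional \code{diet_offsets} (per-diet named coefficient
#'   increments, to inject diet effects).
#' @param sem_shape,sem_mean gamma shape and mean (g/d) for simulated SEm;
#'   shape 20 gives inverse-SEm^2 weights a CV of about 0.5.
#' @param pseudo_rep divisor applied as \code{sqrt(pseudo_rep)} to the
#'   residual SD, mimicking treatment means built from several animals.
#' @param bounds truncation bounds keeping covariates physiological.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_studies = c(TMR = 38L, PASTURE = 7L),
                       means_per_study = c(2L, 5L),
                       covariate_profiles = .default_profiles(),
                       covariate_correlations = .default_correlations(),
                       within_split = 0.3,
                       truth = .default_truth(),
                       sem_shape = 20,
                       sem_mean = 10,
                       pseudo_rep = 1,
                       bounds = list(mun_mgdl = c(2, 40),
                                     bw_kg = c(300, 900),
                                     dmi_kg = c(5, 35),
                                     cp_pct = c(8, 30))) {
  ev <- eigen(covariate_correlations, symmetric = TRUE, only.values = TRUE)
  if (any(ev$values < -1e-8)) {
    stop("covariate correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  stopifnot(all(n_studies >= 1), length(means_per_study) == 2L,
            means_per_study[1] >= 1, means_per_study[2] >= means_per_study[1],
            within_split > 0, within_split < 1,
            truth$var_study >= 0, truth$var_resid > 0,
            sem_shape > 0, sem_mean > 0, pseudo_rep >= 1)
  structure(list(seed = as.integer(seed), n_studies = n_studies,
                 means_per_study = as.integer(means_per_study),
                 covariate_profiles = covariate_profiles,
                 covariate_correlations = covariate_correlations,
                 within_split = within_split, truth = truth,
                 sem_shape = sem_shape, sem_mean = sem_mean,
                 pseudo_rep = pseudo_rep, bounds = bounds),
            class = "sim_config")
}

#' Generate a synthetic study table of treatment means
#'
#' Covariates follow a two-level structure: each study draws a mean vector
#' from its diet profile (the between-study share of the covariance), and
#' each treatment mean adds a within-study deviation (the remaining
#' share), then truncates to the configured physiological bounds. The
#' response is the generating equation's linear predictor plus a study
#' random intercept and a residual scaled by \code{1/sqrt(pseudo_rep)};
#' per-BW generating equations produce the response on the UN/BW scale,
#' which is then multiplied by BW. SEm values are drawn from the gamma
#' law. Deterministic for a fixed seed; the caller's RNG is untouched.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list: \code{table} (a validated \code{study_table} with
#'   \code{un_sem} and derived \code{n_intake_gd}) and \code{truth} (the
#'   generating parameters, echoed).
#' @export
simulate_study_table <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  vars <- c("mun_mgdl", "bw_kg", "dmi_kg", "cp_pct")
  with_preserved_rng(config$seed, {
    rows <- list()
    for (diet in names(config$n_studies)) {
      prof <- config$covariate_profiles[[diet]]
      S <- diag(prof$sd[vars]) %*% config$covariate_correlations %*%
        diag(prof$sd[vars])
      dimnames(S) <- list(vars, vars)
      S_between <- (1 - config$within_split) * S
      S_within <- config$within_split * S
      eq <- config$truth$equation
      if (!is.null(config$truth$diet_offsets)) {
        off <- config$truth$diet_offsets[[diet]]
        if (!is.null(off)) {
          if (eq$diet_specific) {
            stop("diet_offsets with an already diet-specific equation is ",
                 "not supported", call. = FALSE)
          }
          terms <- eq$terms
          for (nmo in names(off)) {
            terms[nmo] <- (if (nmo %in% names(terms)) terms[[nmo]] else 0) +
              off[[nmo]]
          }
          eq <- structure(utils::modifyList(unclass(eq),
                                            list(terms = terms,
                                                 requires = union(eq$requires,
                                                   setdiff(names(off),
                                                           "intercept")))),
                          class = "coefficient_set")
        }
      }
      for (s in seq_len(config$n_studies[[diet]])) {
        sid <- sprintf("10.1000/synth.%s.%03d", tolower(diet), s)
        k <- sample(seq(config$means_per_study[1], config$means_per_study[2]),
                    1L)
        mu_s <- MASS::mvrnorm(1L, mu = prof$mean[vars], Sigma = S_between)
        dev <- MASS::mvrnorm(k, mu = rep(0, 4), Sigma = S_within)
        if (k == 1L) dev <- matrix(dev, nrow = 1L)
        covs <- sweep(dev, 2L, mu_s, "+")
        colnames(covs) <- vars
        for (v in vars) {
          covs[, v] <- pmin(pmax(covs[, v], config$bounds[[v]][1]),
                            config$bounds[[v]][2])
        }
        df <- as.data.frame(covs)
        df$diet <- diet
        df$study_id <- sid
        u_s <- stats::rnorm(1L, 0, sqrt(config$truth$var_study))
        e <- stats::rnorm(k, 0, sqrt(config$truth$var_resid)) /
          sqrt(config$pseudo_rep)
        linpred <- suppressWarnings(predict_un(eq, df)) # g/d scale
        make_resp <- function(u, e) {
          if (eq$per_bw) (linpred / df$bw_kg + u + e) * df$bw_kg
          else linpred + u + e
        }
        resp <- make_resp(u_s, e)
        # UN is physically positive: redraw the noise for the rare record
        # whose draw lands at or below a 5 g/d floor (redrawing the study
        # intercept too if the whole study is pathological)
        tries <- 0L
        while (any(resp <= 5) && tries < 100L) {
          bad <- resp <= 5
          e[bad] <- stats::rnorm(sum(bad), 0,
                                 sqrt(config$truth$var_resid)) /
            sqrt(config$pseudo_rep)
          if (tries >= 20L) {
            u_s <- stats::rnorm(1L, 0, sqrt(config$truth$var_study))
          }
          resp <- make_resp(u_s, e)
          tries <- tries + 1L
        }
        df$un_gd <- resp
        df$un_sem <- stats::rgamma(k, shape = config$sem_shape,
                                   scale = config$sem_mean / config$sem_shape)
        df$n_intake_gd <- df$cp_pct * df$dmi_kg * 10 / 6.25
        rows[[sid]] <- df
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = study_table(tab, provenance = sprintf(
           "synthetic treatment means (seed %d)", config$seed),
           require_sem = TRUE),
         truth = config$truth)
  })
}

#' Inject a known mean and/or linear prediction bias into observed UN
#'
#' Replaces observed UN by \code{un_gd + mean_shift + linear_coef *
#' (predicted - mean(predicted))}, optionally restricted to one diet type.
#' The predicted values (and their grand mean, taken over the whole table
#' to match the centering used by \code{\link{assess_bias}}) come from the
#' reference equation \code{eq}. Used to build fixtures with a known bias
#' that the bias analysis should recover.
#'
#' @param table a \code{study_table}.
#' @param mean_shift additive shift, g/d.
#' @param linear_coef slope applied to the centered predictions.
#' @param diet \code{NULL} (both diets) or \code{"TMR"}/\code{"PASTURE"}.
#' @param eq equation id or \code{coefficient_set} generating the
#'   predictions.
#' @return The modified \code{study_table}.
#' @export
inject_bias <- function(table, mean_shift = 0, linear_coef = 0, diet = NULL,
                        eq = "EQ7") {
  stopifnot(inherits(table, "study_table"))
  pred <- predict_un(eq, table)
  shift <- mean_shift + linear_coef * (pred - mean(pred))
  idx <- if (is.null(diet)) {
    rep(TRUE, nrow(table))
  } else {
    as.character(table$diet) == match.arg(diet, .diet_levels)
  }
  table$un_gd[idx] <- table$un_gd[idx] + shift[idx]
  table
}
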