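# Development of new UN prediction equations on the training set: four
# candidate model families with diet-type interactions, backward
# elimination of non-significant terms under a marginality (hierarchy)
# constraint, and conversion of the surviving fit to a prediction-ready
# coefficient set.

#' The four candidate model families
#'
#' M4 models UN/BW on MUN with a diet interaction; M5 models UN on MUN, CP
#' and DMI, each interacting with diet; M6 adds BW; M7 models UN/BW on
#' MUN, CP and DMI with diet interactions. Per-BW families divide the
#' response by body weight before fitting and multiply back through at
#' prediction time.
#'
#' @return Data frame with \code{family}, \code{response},
#'   \code{covariates} (comma-separated), \code{per_bw}.
#' @export
candidate_families <- function() {
  data.frame(
    family = c("M4", "M5", "M6", "M7"),
    response = c("un_per_bw", "un_gd", "un_gd", "un_per_bw"),
    covariates = c("mun_mgdl",
                   "mun_mgdl,cp_pct,dmi_kg",
                   "mun_mgdl,cp_pct,dmi_kg,bw_kg",
                   "mun_mgdl,cp_pct,dmi_kg"),
    per_bw = c(TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

family_terms <- function(family) {
  fam <- candidate_families()
  row <- fam[fam$family == family, ]
  if (nrow(row) != 1L) {
    stop("unknown model family; expected one of ",
         paste(fam$family, collapse = ", "), call. = FALSE)
  }
  covs <- strsplit(row$covariates, ",")[[1]]
  list(response = row$response, per_bw = row$per_bw, covariates = covs,
       terms = canonical_term(c(covs, "diet", paste0(covs, ":diet"))))
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# canonical term label: interaction components in sorted order, so labels
# agree regardless of the order terms() reports them in
canonical_term <- function(term) {
  vapply(term, function(tm) paste(sort(term_vars(tm)), collapse = ":"),
         character(1), USE.NAMES = FALSE)
}

build_rhs_formula <- function(response, terms, intercept) {
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  if (!intercept) rhs <- paste(rhs, "- 1")
  stats::as.formula(paste(response, "~", rhs))
}

# p-value per model term from a wlmm_fit: the coefficient t-test when the
# term spans one design column, otherwise a joint Wald F test.
term_p_from_fit <- function(fit, data) {
  mf <- stats::model.frame(fit$formula, data = data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  assign <- attr(X, "assign")
  labels <- canonical_term(attr(stats::terms(fit$formula), "term.labels"))
  out <- list()
  if (any(assign == 0L)) {
    out[["(Intercept)"]] <- fit$p_values[["(Intercept)"]]
  }
  for (i in seq_along(labels)) {
    idx <- which(assign == i)
    if (length(idx) == 1L) {
      out[[labels[i]]] <- unname(fit$p_values[idx])
    } else {
      b <- fit$coefficients[idx]
      Vb <- fit$vcov[idx, idx, drop = FALSE]
      Fstat <- drop(t(b) %*% solve(Vb, b)) / length(idx)
      out[[labels[i]]] <- stats::pf(Fstat, length(idx), fit$df_denominator,
                                    lower.tail = FALSE)
    }
  }
  unlist(out)
}

#' Backward elimination of fixed-effect terms
#'
#' Starting from a candidate family's full model (all covariates, diet
#' main effect, and covariate-by-diet interactions) fitted by
#' \code{\link{fit_wlmm}} on the training set, terms with p above
#' \code{alpha} are eliminated. A term is removable only if no surviving
#' higher-order term contains it (marginality), with the intercept always
#' removable. In \code{"sequential"} mode the single least significant
#' removable term is dropped and the model refitted, until every removable
#' term is significant; \code{"block"} mode drops all non-significant
#' removable terms at once per refit. Ties (equal p) break lexicographic
#' on the term name, so the procedure is deterministic and invariant to
#' record and term order.
#'
#' @param train training \code{study_table} containing both diet types.
#' @param family one of \code{"M4"}, \code{"M5"}, \code{"M6"}, \code{"M7"}.
#' @param alpha removal threshold for two-sided p (default 0.05).
#' @param mode \code{"sequential"} (default) or \code{"block"}.
#' @param weighted use SEm weighting (default).
#' @return An object of class \code{"developed_model"}: \code{family},
#'   \code{response}, \code{per_bw}, \code{final_terms},
#'   \code{has_intercept}, \code{fit} (the final \code{wlmm_fit}),
#'   \code{eliminated} (data frame of \code{term}, \code{p_at_removal} in
#'   removal order), \code{alpha}, \code{mode}.
#' @export
develop_model <- function(train, family = c("M4", "M5", "M6", "M7"),
                          alpha = 0.05, mode = c("sequential", "block"),
                          weighted = TRUE) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha <= 1)
  if (nlevels(droplevels(train$diet)) < 2L) {
    stop("training table must contain both diet types", call. = FALSE)
  }
  spec <- family_terms(family)
  d <- as.data.frame(train)
  d$diet <- droplevels(d$diet)
  if (spec$per_bw) d$un_per_bw <- d$un_gd / d$bw_kg
  w <- if (weighted) {
    validate_study_table(as.data.frame(train), require_sem = TRUE)
    build_weights(train$un_sem)
  } else {
    rep(1, nrow(train))
  }

  terms <- sort(spec$terms)
  has_intercept <- TRUE
  eliminated <- data.frame(term = character(0), p_at_removal = numeric(0),
                           stringsAsFactors = FALSE)

  repeat {
    if (length(terms) == 0L && !has_intercept) {
      stop("backward elimination removed every term: degenerate model",
           call. = FALSE)
    }
    # With no intercept and no diet main effect, R expands a
    # covariate-by-diet interaction to full dummy coding (one slope per
    # diet), which aliases the covariate main effect. The main effect is
    # then absorbed into the per-diet slopes: it stays in the logical term
    # list but leaves the formula.
    absorbed <- character(0)
    if (!has_intercept && !("diet" %in% terms)) {
      ixn_covs <- unlist(lapply(terms[grepl(":", terms, fixed = TRUE)],
                                function(tm) setdiff(term_vars(tm), "diet")))
      absorbed <- intersect(terms, ixn_covs)
    }
    fml <- build_rhs_formula(spec$response, setdiff(terms, absorbed),
                             has_intercept)
    fit <- fit_wlmm(fml, d, group = "study_id", weights = w)
    pvals <- term_p_from_fit(fit, d)

    # Marginality: a covariate main effect stays while any surviving
    # interaction contains it. The diet main effect is intercept-like (it
    # encodes per-diet intercepts), so it is removable even while
    # covariate-by-diet interactions survive -- the alternative would
    # forbid the zero-intercept, diet-specific-slope form that this family
    # of models can legitimately reach.
    removable <- character(0)
    if (has_intercept) removable <- "(Intercept)"
    for (tm in terms) {
      if (identical(tm, "diet")) {
        removable <- c(removable, tm)
        next
      }
      contained <- vapply(setdiff(terms, tm), function(other) {
        all(term_vars(tm) %in% term_vars(other))
      }, logical(1))
      if (!any(contained)) removable <- c(removable, tm)
    }
    cand_p <- pvals[removable]
    cand_p <- cand_p[cand_p > alpha]
    if (length(cand_p) == 0L) break
    drop_terms <- if (mode == "sequential") {
      ord <- order(-cand_p, names(cand_p))
      names(cand_p)[ord][1L]
    } else {
      names(cand_p)[order(-cand_p, names(cand_p))]
    }
    for (tm in drop_terms) {
      eliminated <- rbind(eliminated,
                          data.frame(term = tm, p_at_removal = unname(pvals[tm]),
                                     stringsAsFactors = FALSE))
      if (tm == "(Intercept)") has_intercept <- FALSE else {
        terms <- setdiff(terms, tm)
      }
    }
  }

  structure(list(family = family, response = spec$response,
                 per_bw = spec$per_bw, final_terms = terms,
                 has_intercept = has_intercept, fit = fit,
                 eliminated = eliminated, alpha = alpha, mode = mode),
            class = "developed_model")
}

#' @export
print.developed_model <- function(x, ...) {
  cat(sprintf("Developed model %s: %s ~ %s%s\n", x$family, x$response,
              if (length(x$final_terms)) paste(x$final_terms, collapse = " + ")
              else "1",
              if (x$has_intercept) "" else " (no intercept)"))
  if (nrow(x$eliminated) > 0L) {
    cat("Eliminated:",
        paste(sprintf("%s (p = %.2g)", x$eliminated$term,
                      x$eliminated$p_at_removal), collapse = ", "), "\n")
  }
  print(x$fit)
  invisible(x)
}

#' Convert a developed model into a prediction-ready coefficient set
#'
#' Re-expresses the surviving fixed effects as a
#' \code{coefficient_set} usable with \code{\link{predict_un}}. A per-BW
#' response is re-expressed on the UN g/d scale by multiplying through by
#' BW (the coefficients are unchanged; the prediction is scaled). If diet
#' terms survive, diet-specific coefficient vectors are formed for both
#' diet levels, with standard errors of combined (reference + offset)
#' coefficients propagated from the coefficient covariance.
#'
#' @param model a \code{developed_model}.
#' @return A \code{coefficient_set}.
#' @export
finalize_equation <- function(model) {
  stopifnot(inherits(model, "developed_model"))
  fit <- model$fit
  cf <- fit$coefficients
  rhs <- stats::delete.response(stats::terms(fit$formula))
  covs <- setdiff(all.vars(rhs), "diet")
  uses_diet <- "diet" %in% all.vars(rhs)
  has_const <- model$has_intercept ||
    any(model$final_terms == "diet")   # per-diet intercepts count

  # a design row at given covariate values / diet level, in the fitted
  # column order, robust to whatever dummy coding the final formula uses
  design_row <- function(vals, diet_level) {
    nd <- as.data.frame(as.list(vals))
    names(nd) <- covs
    if (length(covs) == 0L) nd <- data.frame(row.names = 1L)
    if (uses_diet) {
      nd$diet <- factor(diet_level, levels = .diet_levels)
    }
    mm <- stats::model.matrix(rhs, nd,
                              xlev = if (uses_diet) list(diet = .diet_levels))
    mm[1L, names(cf)]
  }

  extract_level <- function(diet_level) {
    zero <- stats::setNames(rep(0, length(covs)), covs)
    c0 <- design_row(zero, diet_level)
    terms <- numeric(0)
    ses <- numeric(0)
    if (has_const) {
      terms["intercept"] <- sum(c0 * cf)
      ses["intercept"] <- sqrt(drop(t(c0) %*% fit$vcov %*% c0))
    }
    for (cv in covs) {
      unit <- zero
      unit[cv] <- 1
      cj <- design_row(unit, diet_level) - c0
      terms[cv] <- sum(cj * cf)
      ses[cv] <- sqrt(drop(t(cj) %*% fit$vcov %*% cj))
    }
    list(terms = terms, se = ses)
  }

  diet_specific <- uses_diet
  requires <- covs
  if (model$per_bw) requires <- union(requires, "bw_kg")

  if (!diet_specific) {
    lv <- extract_level("TMR")
    cs <- list(id = paste0("DEV_", model$family),
               description = sprintf("developed %s model (no diet terms)",
                                     model$family),
               response = model$response, per_bw = model$per_bw,
               diet_specific = FALSE, terms = lv$terms, se = lv$se,
               requires = requires)
    return(structure(cs, class = "coefficient_set"))
  }
  tmr <- extract_level("TMR")
  pas <- extract_level("PASTURE")
  cs <- list(id = paste0("DEV_", model$family),
             description = sprintf("developed %s model (diet-specific)",
                                   model$family),
             response = model$response, per_bw = model$per_bw,
             diet_specific = TRUE,
             terms = list(TMR = tmr$terms, PASTURE = pas$terms),
             se = list(TMR = tmr$se, PASTURE = pas$se),
             requires = union(requires, "diet"))
  structure(cs, class = "coefficient_set")
}
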