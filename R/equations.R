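# Closed-form UN prediction equations: three published (EQ1-EQ3) and four
# developed by the meta-regression workflow (EQ4-EQ7), with the
# renal-clearance reading of per-BW MUN slopes.

# Registry of published coefficient sets. Coefficients are stored exactly
# as printed; per-BW responses are multiplied through by BW at prediction
# time. Standard errors, where published, are kept for reporting only.
.equation_registry <- function() {
  list(
    EQ1 = list(
      id = "EQ1",
      description = "UN (g/d) = 12.54 x MUN",
      response = "un_gd",
      per_bw = FALSE, diet_specific = FALSE,
      terms = c(mun_mgdl = 12.54),
      se = NULL,
      requires = "mun_mgdl"),
    EQ2 = list(
      id = "EQ2",
      description = "UN (g/d)/BW (kg) = 0.0259 x MUN",
      response = "un_per_bw",
      per_bw = TRUE, diet_specific = FALSE,
      terms = c(mun_mgdl = 0.0259),
      se = NULL,
      requires = c("mun_mgdl", "bw_kg")),
    EQ3 = list(
      id = "EQ3",
      description = "UN (g/d) = -148.8 + 8.06 x MUN + 8.91 x CP + 4.06 x DMI",
      response = "un_gd",
      per_bw = FALSE, diet_specific = FALSE,
      terms = c(intercept = -148.8, mun_mgdl = 8.06, cp_pct = 8.91,
                dmi_kg = 4.06),
      se = NULL,
      requires = c("mun_mgdl", "cp_pct", "dmi_kg")),
    EQ4 = list(
      id = "EQ4",
      description = paste("UN (g/d)/BW (kg) = 0.0214 x MUN (TMR) /",
                          "0.0240 x MUN (pasture)"),
      response = "un_per_bw",
      per_bw = TRUE, diet_specific = TRUE,
      terms = list(TMR = c(mun_mgdl = 0.0214),
                   PASTURE = c(mun_mgdl = 0.0240)),
      se = list(TMR = c(mun_mgdl = 0.00156),
                PASTURE = c(mun_mgdl = 0.000704)),
      requires = c("mun_mgdl", "bw_kg", "diet")),
    EQ5 = list(
      id = "EQ5",
      description = "UN (g/d) = -209.4 + 6.8 x MUN + 12.4 x CP + 4.8 x DMI",
      response = "un_gd",
      per_bw = FALSE, diet_specific = FALSE,
      terms = c(intercept = -209.4, mun_mgdl = 6.8, cp_pct = 12.4,
                dmi_kg = 4.8),
      se = c(intercept = 24.40, mun_mgdl = 0.80, cp_pct = 1.51,
             dmi_kg = 0.74),
      requires = c("mun_mgdl", "cp_pct", "dmi_kg")),
    EQ6 = list(
      id = "EQ6",
      description = paste("UN (g/d) = -281.3 + 6.7 x MUN + 13.2 x CP +",
                          "2.8 x DMI + 0.16 x BW"),
      response = "un_gd",
      per_bw = FALSE, diet_specific = FALSE,
      terms = c(intercept = -281.3, mun_mgdl = 6.7, cp_pct = 13.2,
                dmi_kg = 2.8, bw_kg = 0.16),
      se = c(intercept = 31.04, mun_mgdl = 0.77, cp_pct = 1.47,
             dmi_kg = 0.93, bw_kg = 0.046),
      requires = c("mun_mgdl", "cp_pct", "dmi_kg", "bw_kg")),
    EQ7 = list(
      id = "EQ7",
      description = paste("UN (g/d) = [-0.253 + 0.00932 x MUN +",
                          "0.0260 x CP] x BW"),
      response = "un_per_bw",
      per_bw = TRUE, diet_specific = FALSE,
      terms = c(intercept = -0.253, mun_mgdl = 0.00932, cp_pct = 0.0260),
      se = c(intercept = 0.0323, mun_mgdl = 0.00132, cp_pct = 0.00250),
      requires = c("mun_mgdl", "cp_pct", "bw_kg"))
  )
}

#' Identifiers of the bundled UN prediction equations
#'
#' EQ1-EQ3 are previously published equations; EQ4-EQ7 are the equations
#' developed by the weighted meta-regression this package implements, with
#' their published (printed, rounded) coefficients.
#'
#' @return Character vector \code{c("EQ1", ..., "EQ7")}.
#' @export
un_equation_ids <- function() names(.equation_registry())

#' Coefficient set of a bundled prediction equation
#'
#' @param eq equation id, one of \code{\link{un_equation_ids}}.
#' @return A list of class \code{"coefficient_set"}: \code{id},
#'   \code{description}, \code{response} (\code{"un_gd"} or
#'   \code{"un_per_bw"}), \code{per_bw}, \code{diet_specific},
#'   \code{terms} (named coefficients; for a diet-specific equation a list
#'   with one vector per diet), \code{se} (standard errors where
#'   published), \code{requires} (covariates needed for prediction).
#' @export
equation_coefficients <- function(eq) {
  reg <- .equation_registry()
  if (!is.character(eq) || length(eq) != 1L || !eq %in% names(reg)) {
    stop("unknown equation id; expected one of ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  structure(reg[[eq]], class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$id, x$description))
  invisible(x)
}

eval_linear <- function(terms, data) {
  out <- rep(0, nrow(data))
  for (nm in names(terms)) {
    if (nm == "intercept") {
      out <- out + terms[[nm]]
    } else {
      out <- out + terms[[nm]] * data[[nm]]
    }
  }
  out
}

#' Predict urinary nitrogen excretion (g/d)
#'
#' Evaluates one of the bundled equations (or any
#' \code{coefficient_set}, e.g. from \code{\link{finalize_equation}}) on a
#' table of treatment means. Per-BW responses are multiplied through by BW
#' so the return value is always on the g/d scale. Predictions are never
#' truncated; a negative prediction (possible for extreme low covariates
#' under the affine equations) is returned as-is with a warning.
#'
#' @param eq equation id or a \code{coefficient_set}.
#' @param data data frame with the covariate columns the equation requires
#'   (canonical names, see \code{\link{study_table_schema}}); a
#'   diet-specific equation additionally needs \code{diet}.
#' @return Numeric vector of predicted UN, g/d.
#' @export
predict_un <- function(eq, data) {
  cs <- if (inherits(eq, "coefficient_set")) eq else equation_coefficients(eq)
  stopifnot(is.data.frame(data))
  need <- setdiff(cs$requires, names(data))
  if (length(need) > 0L) {
    stop(sprintf("equation %s requires missing covariate(s): %s",
                 cs$id, paste(need, collapse = ", ")), call. = FALSE)
  }
  for (nm in setdiff(cs$requires, "diet")) {
    if (anyNA(data[[nm]])) {
      stop(sprintf("equation %s: covariate '%s' has missing values",
                   cs$id, nm), call. = FALSE)
    }
  }
  if (cs$diet_specific) {
    diet <- as.character(normalize_diet(data$diet))
    pred <- numeric(nrow(data))
    for (d in unique(diet)) {
      idx <- diet == d
      pred[idx] <- eval_linear(cs$terms[[d]], data[idx, , drop = FALSE])
    }
  } else {
    pred <- eval_linear(cs$terms, data)
  }
  if (cs$per_bw) pred <- pred * data$bw_kg
  if (any(pred < 0)) {
    warning(sprintf("equation %s produced %d negative UN prediction(s); %s",
                    cs$id, sum(pred < 0),
                    "returned untruncated (out-of-domain extrapolation)"),
            call. = FALSE)
  }
  pred
}

#' Renal-clearance interpretation of a per-BW MUN slope
#'
#' A slope b in (g UN/d) per (kg BW x mg MUN/dL) corresponds to clearing
#' \code{b * 100} liters of fluid per kg BW per day, since 1 mg/dL =
#' 0.01 g/L makes the unit conversion an exact factor of 100.
#'
#' @param coefficient positive per-BW MUN slope.
#' @return Clearance, L/(kg BW x d).
#' @export
renal_clearance_per_bw <- function(coefficient) {
  if (any(!is.finite(coefficient) | coefficient <= 0)) {
    stop("coefficient must be finite and > 0", call. = FALSE)
  }
  coefficient * 100
}

#' Percent difference between two slopes
#'
#' @param a reference slope (nonzero).
#' @param b comparison slope.
#' @return \code{100 * (b - a) / a}.
#' @export
coefficient_percent_difference <- function(a, b) {
  if (any(!is.finite(a) | a == 0)) {
    stop("reference slope 'a' must be finite and nonzero", call. = FALSE)
  }
  100 * (b - a) / a
}
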