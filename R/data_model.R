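# Treatment-mean data schema, unit conversions, and the study-level split.

#' Required and optional columns of a treatment-mean table
#'
#' The unit of analysis is the treatment mean: one experimental group's
#' average outcome in a source study. Required columns (all numeric unless
#' noted): \code{study_id} (character, the source experiment's DOI),
#' \code{diet} (\code{"TMR"} or \code{"PASTURE"}), \code{un_gd} (urinary N,
#' g/d), \code{mun_mgdl} (milk urea N, mg/dL), \code{bw_kg}, \code{dmi_kg},
#' \code{cp_pct} (crude protein, \% of DM). Optional: \code{un_sem}
#' (standard error of the treatment-mean UN, g/d; required when weighting),
#' \code{ndf_pct}, \code{n_intake_gd}, \code{milk_yield_kgd}, \code{dim_d}.
#'
#' @return A data frame with columns \code{column}, \code{required},
#'   \code{unit}, \code{description}.
#' @export
study_table_schema <- function() {
  data.frame(
    column = c("study_id", "diet", "un_gd", "un_sem", "mun_mgdl", "bw_kg",
               "dmi_kg", "cp_pct", "ndf_pct", "n_intake_gd",
               "milk_yield_kgd", "dim_d"),
    required = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                 FALSE, FALSE, FALSE),
    unit = c("DOI string", "TMR|PASTURE", "g/d", "g/d", "mg/dL", "kg",
             "kg/d", "% of DM", "% of DM", "g/d", "kg/d", "d"),
    description = c(
      "source experiment identifier; one diet type per study",
      "diet stratum: total mixed ration or fresh forage/pasture",
      "observed urinary nitrogen excretion (response)",
      "standard error of the treatment-mean UN; drives weighting",
      "milk urea nitrogen concentration",
      "body weight",
      "dry matter intake",
      "dietary crude protein",
      "dietary neutral detergent fiber",
      "nitrogen intake",
      "milk yield",
      "days in milk"),
    stringsAsFactors = FALSE
  )
}

.diet_levels <- c("TMR", "PASTURE")

required_columns <- function() {
  sch <- study_table_schema()
  sch$column[sch$required]
}

#' Construct a validated study table of treatment means
#'
#' Coerces a data frame to the canonical treatment-mean layout: checks the
#' schema, validates row-level invariants, maps diet labels to the two
#' canonical levels, and applies the canonical sort (diet, study id,
#' original row order within study) so downstream fits are
#' permutation-stable.
#'
#' @param df data frame carrying at least the required columns of
#'   \code{\link{study_table_schema}}.
#' @param provenance free-text note on where the records came from.
#' @param require_sem if \code{TRUE}, a positive \code{un_sem} is required
#'   on every row (set when SEm weighting will be requested downstream).
#' @return A data frame of class \code{"study_table"}, canonically sorted,
#'   with \code{diet} as a factor with levels TMR, PASTURE and a
#'   \code{provenance} attribute.
#' @export
study_table <- function(df, provenance = "unspecified", require_sem = FALSE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$study_id <- as.character(df$study_id)
  df$diet <- normalize_diet(df$diet)

  validate_study_table(df, require_sem = require_sem)

  # canonical sort: diet, study_id, then original row order within study
  ord <- order(df$diet, df$study_id, seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("study_table", "data.frame")
  df
}

normalize_diet <- function(x) {
  lab <- toupper(trimws(as.character(x)))
  lab[lab %in% c("FF", "FRESH FORAGE", "FORAGE", "GRASS")] <- "PASTURE"
  bad <- !lab %in% .diet_levels
  if (any(bad)) {
    stop("unknown diet label(s): ", paste(unique(lab[bad]), collapse = ", "),
         "; expected TMR or PASTURE", call. = FALSE)
  }
  factor(lab, levels = .diet_levels)
}

#' Validate treatment-mean invariants
#'
#' Checks positivity of UN, MUN, BW and DMI, that CP lies in (0, 100), that
#' every study id carries exactly one diet type, and (optionally) that
#' every row has a positive SEm. Violations are reported with the offending
#' row indices.
#'
#' @param df data frame in study-table layout.
#' @param require_sem require positive \code{un_sem} on every row.
#' @return \code{df}, invisibly, when valid; otherwise an error.
#' @export
validate_study_table <- function(df, require_sem = FALSE) {
  problems <- character(0)
  flag <- function(bad, msg) {
    bad <- which(bad)
    if (length(bad) > 0L) {
      problems <<- c(problems,
                     sprintf("%s (rows %s)", msg,
                             paste(utils::head(bad, 10L), collapse = ", ")))
    }
  }
  num_bad <- function(x) !is.finite(x) | x <= 0
  flag(num_bad(df$un_gd), "un_gd must be finite and > 0")
  flag(num_bad(df$mun_mgdl), "mun_mgdl must be finite and > 0")
  flag(num_bad(df$bw_kg), "bw_kg must be finite and > 0")
  flag(num_bad(df$dmi_kg), "dmi_kg must be finite and > 0")
  flag(!is.finite(df$cp_pct) | df$cp_pct <= 0 | df$cp_pct >= 100,
       "cp_pct must lie in (0, 100)")
  if (require_sem) {
    if (is.null(df$un_sem)) {
      problems <- c(problems, "un_sem column absent but weighting requested")
    } else {
      flag(!is.finite(df$un_sem) | df$un_sem <= 0,
           "un_sem must be finite and > 0 when weighting is requested")
    }
  }
  diets_per_study <- tapply(as.character(df$diet), df$study_id,
                            function(d) length(unique(d)))
  if (any(diets_per_study > 1L)) {
    problems <- c(problems,
                  sprintf("study/studies mapped to more than one diet type: %s",
                          paste(names(diets_per_study)[diets_per_study > 1L],
                                collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stop("invalid study table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(df)
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table: %d treatment means from %d studies (%s)\n",
              nrow(x), length(unique(x$study_id)),
              paste(sprintf("%s: %d", levels(x$diet), table(x$diet)),
                    collapse = ", ")))
  cat(sprintf("Provenance: %s\n", attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited treatment-mean table
#'
#' Reads a comma- or tab-separated text file with a header row, optionally
#' renames columns via \code{col_map}, and validates it into a
#' \code{\link{study_table}}. The delimiter is taken from the file
#' extension (\code{.tsv}/\code{.txt} = tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param col_map named character vector mapping canonical column name to
#'   the name used in the file, e.g. \code{c(mun_mgdl = "MUN")}.
#' @param sep field separator; \code{NULL} to infer from the extension.
#' @param require_sem passed to \code{\link{study_table}}.
#' @param provenance provenance note; defaults to the file path.
#' @return A \code{study_table}.
#' @export
read_treatment_table <- function(path, col_map = NULL, sep = NULL,
                                 require_sem = FALSE, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || any(names(col_map) == "")) {
      stop("col_map must be a fully named character vector", call. = FALSE)
    }
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop("column mapped for '", canon, "' not in file: ", src,
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  num_cols <- setdiff(intersect(study_table_schema()$column, names(df)),
                      c("study_id", "diet"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad) > 0L) {
        stop(sprintf("column '%s': unparsable numeric value(s) at row(s) %s",
                     cl, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
      }
      df[[cl]] <- parsed
    }
  }
  study_table(df, provenance = provenance, require_sem = require_sem)
}

#' Write a study table to a delimited text file
#'
#' @param table a \code{study_table}.
#' @param path output path; extension chooses the delimiter as in
#'   \code{\link{read_treatment_table}}.
#' @return \code{path}, invisibly.
#' @export
write_treatment_table <- function(table, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# --- unit conversions ---------------------------------------------------

# Printed conversion factors are authoritative: milk urea mmol/L -> MUN
# mg/dL divides by 0.357 (the exact molar route, 1/(6.006 * 0.467) =
# 0.35655, rounds to the same divisor), and milk urea mg/dL -> MUN mg/dL
# multiplies by 0.467 (urea is 46.7% N by mass).
.MILK_UREA_MMOL_DIVISOR <- 0.357
.UREA_N_FRACTION <- 0.467
.CP_PER_N <- 6.25

#' Convert milk urea measurements to milk urea nitrogen (mg/dL)
#'
#' @param value non-negative concentration value(s).
#' @param unit unit of \code{value}: \code{"milk_urea_mmol_l"} (divides by
#'   0.357), \code{"milk_urea_mgdl"} (multiplies by 0.467, urea being
#'   46.7\% N), or \code{"mun_mgdl"} (identity).
#' @return MUN in mg/dL.
#' @export
convert_milk_urea_to_mun <- function(value,
                                     unit = c("mun_mgdl", "milk_urea_mmol_l",
                                              "milk_urea_mgdl")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value) | value < 0)) {
    stop("concentration values must be finite and >= 0", call. = FALSE)
  }
  switch(unit,
         mun_mgdl = value,
         milk_urea_mmol_l = value / .MILK_UREA_MMOL_DIVISOR,
         milk_urea_mgdl = value * .UREA_N_FRACTION)
}

#' Dietary crude protein (\% of DM) from nitrogen intake and DMI
#'
#' CP = N x 6.25; the diet's CP concentration is total CP intake over total
#' dry matter intake: \code{100 * n_intake_gd * 6.25 / (dmi_kg * 1000)}.
#'
#' @param n_intake_gd nitrogen intake, g/d (> 0).
#' @param dmi_kg dry matter intake, kg/d (> 0).
#' @return CP as \% of DM.
#' @export
cp_from_n_intake <- function(n_intake_gd, dmi_kg) {
  if (any(!is.finite(n_intake_gd) | n_intake_gd <= 0) ||
      any(!is.finite(dmi_kg) | dmi_kg <= 0)) {
    stop("n_intake_gd and dmi_kg must be finite and > 0", call. = FALSE)
  }
  100 * (n_intake_gd * .CP_PER_N) / (dmi_kg * 1000)
}

#' Body weight from DMI expressed as a percentage of BW
#'
#' @param dmi_kg dry matter intake, kg/d (> 0).
#' @param dmi_pct_bw DMI as \% of body weight (> 0).
#' @return Body weight, kg.
#' @export
bw_from_dmi_fraction <- function(dmi_kg, dmi_pct_bw) {
  if (any(!is.finite(dmi_kg) | dmi_kg <= 0) ||
      any(!is.finite(dmi_pct_bw) | dmi_pct_bw <= 0)) {
    stop("dmi_kg and dmi_pct_bw must be finite and > 0", call. = FALSE)
  }
  100 * dmi_kg / dmi_pct_bw
}

# --- train/test split ---------------------------------------------------

#' Diet-stratified train/test split by study
#'
#' Studies (never individual treatment means) are randomly assigned so the
#' test set holds exactly \code{n_test_per_diet} studies of each diet type;
#' all treatment means of a study travel together, so train and test share
#' no study. Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param table a \code{study_table}.
#' @param n_test_per_diet number of studies held out per diet type.
#' @param seed integer seed for the draw.
#' @return A list with \code{study_table} elements \code{train} and
#'   \code{test}.
#' @export
split_by_study <- function(table, n_test_per_diet, seed = 1L) {
  stopifnot(inherits(table, "study_table"),
            n_test_per_diet >= 0, n_test_per_diet == round(n_test_per_diet))
  studies <- unique(data.frame(study_id = table$study_id,
                               diet = as.character(table$diet),
                               stringsAsFactors = FALSE))
  test_ids <- character(0)
  if (n_test_per_diet > 0L) {
    test_ids <- with_preserved_rng(seed, {
      unlist(lapply(.diet_levels, function(d) {
        ids <- sort(studies$study_id[studies$diet == d])
        if (length(ids) <= n_test_per_diet) {
          stop(sprintf(
            "diet stratum %s has %d studies; need more than n_test_per_diet = %d",
            d, length(ids), n_test_per_diet), call. = FALSE)
        }
        sample(ids, n_test_per_diet)
      }), use.names = FALSE)
    })
  }
  in_test <- table$study_id %in% test_ids
  prov <- attr(table, "provenance") %||% "unspecified"
  list(
    train = study_table(as.data.frame(table)[!in_test, , drop = FALSE],
                        provenance = paste0(prov, " [training subset]")),
    test = if (any(in_test)) {
      study_table(as.data.frame(table)[in_test, , drop = FALSE],
                  provenance = paste0(prov, " [test subset]"))
    } else {
      tt <- as.data.frame(table)[in_test, , drop = FALSE]
      attr(tt, "provenance") <- paste0(prov, " [test subset]")
      class(tt) <- c("study_table", "data.frame")
      tt
    }
  )
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
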