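# End-to-end orchestration: evaluate published equations, split by study,
# develop new equations on the training set, validate on the test set,
# and write JSON + text reports with a run manifest.

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

bias_report_as_list <- function(rep) {
  list(equation = rep$equation,
       per_diet = rep$per_diet,
       interaction_p_mean = rep$interaction_p_mean,
       interaction_p_linear = rep$interaction_p_linear)
}

#' Run the full UN meta-regression pipeline
#'
#' Chains the four analysis stages: (1) mean/linear bias assessment of the
#' published equations on the full table, with the residual-vs-covariate
#' regression grid; (2) diet-stratified train/test split by study; (3)
#' backward-eliminated model development of the four candidate families on
#' the training set; (4) agreement evaluation of the developed equations
#' on the held-out test set. Reports are written as JSON (machine
#' interface) plus a plain-text summary, together with a run manifest
#' (inputs, seed, package version, configuration) from which the
#' artifacts are bit-identically regenerable.
#'
#' @param table a \code{study_table}; or \code{NULL} to read from
#'   \code{path}.
#' @param path delimited input file, used when \code{table} is
#'   \code{NULL}.
#' @param col_map column mapping for \code{\link{read_treatment_table}}.
#' @param outdir output directory, created if needed.
#' @param seed integer seed for the train/test split.
#' @param n_test_per_diet studies held out per diet type.
#' @param published_eqs equation ids assessed for bias in stage 1.
#' @param families candidate families developed in stage 3.
#' @param alpha removal threshold for backward elimination.
#' @param weighted use SEm weighting throughout.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a list with \code{bias_reports},
#'   \code{residual_regressions}, \code{split}, \code{developed},
#'   \code{finalized}, \code{validation}, \code{manifest}.
#' @export
run_un_pipeline <- function(table = NULL, path = NULL, col_map = NULL,
                            outdir = tempfile("un_pipeline_"),
                            seed = 1L, n_test_per_diet = 3L,
                            published_eqs = c("EQ1", "EQ2", "EQ3"),
                            families = c("M4", "M5", "M6", "M7"),
                            alpha = 0.05, weighted = TRUE, verbose = TRUE) {
  log_msg <- function(...) if (verbose) message("[un-pipeline] ", sprintf(...))
  if (is.null(table)) {
    if (is.null(path)) stop("supply either table or path", call. = FALSE)
    log_msg("reading %s", path)
    table <- read_treatment_table(path, col_map = col_map,
                                  require_sem = weighted)
  }
  stopifnot(inherits(table, "study_table"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  log_msg("stage 1/4: bias assessment of %s on %d treatment means",
          paste(published_eqs, collapse = ", "), nrow(table))
  bias_reports <- lapply(published_eqs, function(eq) {
    assess_bias(table, eq, weighted = weighted)
  })
  names(bias_reports) <- published_eqs
  resid_grid <- do.call(rbind, lapply(published_eqs, function(eq) {
    do.call(rbind, lapply(c("mun_mgdl", "cp_pct", "dmi_kg", "bw_kg"),
                          function(cv) {
      residual_covariate_regression(table, eq, cv, weighted = weighted)
    }))
  }))
  write_json_report(list(bias = lapply(bias_reports, bias_report_as_list),
                         residual_regressions = resid_grid),
                    file.path(outdir, "evaluate_published.json"))

  log_msg("stage 2/4: splitting %d studies (%d per diet to test, seed %d)",
          length(unique(table$study_id)), n_test_per_diet, seed)
  split <- split_by_study(table, n_test_per_diet = n_test_per_diet,
                          seed = seed)

  log_msg("stage 3/4: developing families %s on %d training means",
          paste(families, collapse = ", "), nrow(split$train))
  developed <- lapply(families, function(fam) {
    develop_model(split$train, family = fam, alpha = alpha,
                  weighted = weighted)
  })
  names(developed) <- families
  finalized <- lapply(developed, finalize_equation)
  write_json_report(
    lapply(developed, function(m) {
      list(family = m$family, response = m$response,
           final_terms = m$final_terms, has_intercept = m$has_intercept,
           eliminated = m$eliminated, fit = fit_report(m$fit))
    }),
    file.path(outdir, "developed_models.json"))

  log_msg("stage 4/4: validating on %d held-out means from %d studies",
          nrow(split$test), length(unique(split$test$study_id)))
  validation <- evaluate_on_test(split$test, eqs = unname(finalized))
  write_json_report(validation, file.path(outdir, "validation.json"))

  manifest <- list(
    package = "munpredict",
    version = as.character(utils::packageVersion("munpredict")),
    seed = seed,
    n_test_per_diet = n_test_per_diet,
    alpha = alpha,
    weighted = weighted,
    published_eqs = published_eqs,
    families = families,
    input = list(path = if (is.null(path)) NA else path,
                 n_records = nrow(table),
                 n_studies = length(unique(table$study_id)),
                 provenance = attr(table, "provenance") %||% "unspecified"),
    test_studies = sort(unique(split$test$study_id))
  )
  write_json_report(manifest, file.path(outdir, "manifest.json"))

  txt <- file.path(outdir, "summary.txt")
  con <- file(txt, open = "wt")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  cat("UN meta-regression pipeline summary\n")
  cat("===================================\n\n")
  print(table[0, ])
  cat(sprintf("\nInput: %d treatment means, %d studies\n\n", nrow(table),
              length(unique(table$study_id))))
  cat("-- Published-equation bias --\n")
  for (b in bias_reports) print(b)
  cat("\n-- Developed equations --\n")
  for (m in developed) print(m)
  cat("\n-- Test-set agreement --\n")
  print(validation$agreement, row.names = FALSE)
  cat("\n-- Test-set descriptives --\n")
  print(validation$descriptives, row.names = FALSE)
  sink()
  close(con)
  on.exit(NULL)
  log_msg("reports written to %s", outdir)

  invisible(list(bias_reports = bias_reports,
                 residual_regressions = resid_grid,
                 split = split, developed = developed,
                 finalized = finalized, validation = validation,
                 manifest = manifest, outdir = outdir))
}
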