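test_that("milk urea conversions use the printed factors", {
  # 1 mmol/L milk urea -> MUN mg/dL divides by 0.357
  expect_equal(convert_milk_urea_to_mun(1, "milk_urea_mmol_l"), 1 / 0.357)
  # milk urea mg/dL -> MUN mg/dL multiplies by 0.467 (urea is 46.7% N)
  expect_equal(convert_milk_urea_to_mun(10, "milk_urea_mgdl"), 4.67)
  expect_equal(convert_milk_urea_to_mun(12.3, "mun_mgdl"), 12.3)
  expect_equal(convert_milk_urea_to_mun(0, "milk_urea_mmol_l"), 0)
  expect_error(convert_milk_urea_to_mun(1, "mol_l"))
  expect_error(convert_milk_urea_to_mun(-1, "mun_mgdl"), "finite and >= 0")
})

test_that("conversion round-trips and the molar route agree with the divisor", {
  # MUN mg/dL -> milk urea mmol/L (x 0.357) -> back recovers the input
  mun <- c(3.7, 11.2, 28.9)
  back <- convert_milk_urea_to_mun(mun * 0.357, "milk_urea_mmol_l")
  expect_equal(back, mun, tolerance = 1e-9)
  # molar route: 1 mmol/L urea = 6.006 mg/dL urea, x 0.467 N fraction;
  # its reciprocal rounds to the printed divisor
  expect_equal(round(1 / (6.006 * 0.467), 3), 0.357)
})

test_that("CP from N intake matches hand arithmetic and printed profiles", {
  # printed TMR complete-set values: N intake 594.6 g/d, DMI 22.2 kg/d
  # reproduce the printed CP of 16.7% DM
  expect_equal(round(cp_from_n_intake(594.6, 22.2), 1), 16.7)
  expect_equal(cp_from_n_intake(160, 10), 10)
  expect_error(cp_from_n_intake(0, 10), "> 0")
  expect_error(cp_from_n_intake(100, -1), "> 0")
  # homogeneity: scaling intake and DMI together leaves CP unchanged
  for (k in c(0.5, 2, 13.7)) {
    expect_equal(cp_from_n_intake(594.6 * k, 22.2 * k),
                 cp_from_n_intake(594.6, 22.2))
  }
})

test_that("BW from DMI-as-percent-of-BW inverts the percentage", {
  expect_equal(bw_from_dmi_fraction(18, 3), 600)
  expect_equal(bw_from_dmi_fraction(22, 4), 550)
  expect_error(bw_from_dmi_fraction(18, 0), "> 0")
})

test_that("study tables validate, sort canonically, and round-trip files", {
  tab <- make_small_table()
  expect_s3_class(tab, "study_table")
  expect_identical(nrow(tab), 10L)
  # canonical sort: diet block first, then study id
  expect_true(!is.unsorted(order(tab$diet, tab$study_id)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_treatment_table(tab, path)
  back <- read_treatment_table(path, require_sem = TRUE)
  expect_equal(strip_prov(back), strip_prov(tab), tolerance = 1e-12)
})

test_that("schema and row-level violations are reported with context", {
  df <- as.data.frame(make_small_table())
  # missing mandatory column is named
  expect_error(study_table(df[, setdiff(names(df), "mun_mgdl")]),
               "mun_mgdl")
  # a zero SEm row is flagged with its row index when weighting is requested
  df2 <- df
  df2$un_sem[3] <- 0
  expect_error(study_table(df2, require_sem = TRUE), "un_sem")
  expect_silent(study_table(df2, require_sem = FALSE))
  # non-positive measurements are rejected
  df3 <- df
  df3$un_gd[1] <- -5
  expect_error(study_table(df3), "un_gd")
  # a study cannot carry two diet types
  df4 <- df
  df4$diet[1] <- "PASTURE"
  expect_error(study_table(df4), "more than one diet")
})

test_that("reading maps columns and rejects unparsable numerics", {
  tab <- make_small_table()
  df <- as.data.frame(tab)
  names(df)[names(df) == "mun_mgdl"] <- "MUN"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_treatment_table(path, col_map = c(mun_mgdl = "MUN"))
  expect_equal(back$mun_mgdl, tab$mun_mgdl)
  expect_error(read_treatment_table(path, col_map = c(mun_mgdl = "nope")),
               "nope")

  df$MUN <- as.character(df$MUN)
  df$MUN[4] <- "12,1"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_treatment_table(path, col_map = c(mun_mgdl = "MUN")),
               "unparsable")
})

test_that("the bundled example file loads as a valid study table", {
  path <- system.file("extdata", "synthetic_treatment_means.csv",
                      package = "munpredict")
  tab <- read_treatment_table(path, require_sem = TRUE)
  expect_s3_class(tab, "study_table")
  expect_identical(nrow(tab), 21L)
  expect_identical(length(unique(tab$study_id)), 8L)
})

test_that("study-level split yields the requested stratum counts", {
  # 41 TMR + 10 pasture studies, 3 held out per diet -> 38/7 train, 3/3 test
  sim <- quick_sim(5, n_studies = c(TMR = 41L, PASTURE = 10L),
                   means_per_study = c(3L, 4L))
  tab <- sim$table
  sp <- split_by_study(tab, n_test_per_diet = 3, seed = 11)
  count_studies <- function(t) {
    s <- unique(data.frame(id = t$study_id, diet = as.character(t$diet)))
    table(factor(s$diet, c("TMR", "PASTURE")))
  }
  expect_equal(as.vector(count_studies(sp$train)), c(38, 7))
  expect_equal(as.vector(count_studies(sp$test)), c(3, 3))
  # the split is by study: no overlap, union preserved, records conserved
  expect_length(intersect(sp$train$study_id, sp$test$study_id), 0)
  expect_setequal(c(sp$train$study_id, sp$test$study_id), tab$study_id)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(tab))
})

test_that("split is deterministic in the seed and stable in sizes", {
  tab <- quick_sim(6)$table
  a <- split_by_study(tab, 2, seed = 42)
  b <- split_by_study(tab, 2, seed = 42)
  expect_identical(a$test$study_id, b$test$study_id)
  c <- split_by_study(tab, 2, seed = 43)
  expect_identical(nrow(a$test) + nrow(a$train), nrow(c$test) + nrow(c$train))
  expect_identical(length(unique(c$test$study_id)), 4L)

  empty <- split_by_study(tab, 0, seed = 1)
  expect_identical(nrow(empty$test), 0L)
  expect_equal(strip_prov(empty$train), strip_prov(tab))

  expect_error(split_by_study(tab, 50, seed = 1), "stratum")
})
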