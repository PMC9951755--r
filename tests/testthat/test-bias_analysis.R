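test_that("residuals are observed minus predicted", {
  d <- make_small_table()
  d$un_gd <- predict_un("EQ1", d)
  expect_equal(un_residuals(d, "EQ1"), rep(0, nrow(d)))

  one <- data.frame(un_gd = 130, mun_mgdl = 10)
  expect_equal(un_residuals(one, "EQ1"), 4.6)
  # over-prediction gives a negative residual
  over <- data.frame(un_gd = 100, mun_mgdl = 10)
  expect_lt(un_residuals(over, "EQ1"), 0)
})

test_that("mean centering", {
  expect_equal(mean_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean_center(rep(4.2, 5)), rep(0, 5))
  x <- rnorm(20, 100, 10)
  expect_equal(mean(mean_center(x)), 0, tolerance = 1e-12)
  expect_equal(mean_center(mean_center(x)), mean_center(x))
  expect_error(mean_center(numeric(0)), "empty")
})

test_that("perfect predictions give an all-zero bias report", {
  d <- make_small_table()
  d$un_gd <- predict_un("EQ1", d)
  rep0 <- assess_bias(d, "EQ1")
  expect_equal(rep0$per_diet$mean_bias, c(0, 0))
  expect_equal(rep0$per_diet$linear_bias, c(0, 0))
  expect_equal(rep0$per_diet$rmsep, c(0, 0))
  expect_equal(rep0$per_diet$rpe, c(0, 0))
})

test_that("OLS residuals on a single diet show no mean or linear bias", {
  # fit an equation to the data itself by OLS (no random effect, equal
  # weights); orthogonality of OLS residuals forces both biases to zero
  set.seed(21)
  n <- 40
  d <- data.frame(study_id = sprintf("s%02d", 1:n),  # singleton studies
                  diet = "TMR",
                  mun_mgdl = runif(n, 8, 20),
                  bw_kg = 650, dmi_kg = 22, cp_pct = 17)
  d$un_gd <- 40 + 11 * d$mun_mgdl + rnorm(n, 0, 15)
  ols <- lm(un_gd ~ mun_mgdl, data = d)
  eq <- structure(list(id = "OLSFIT", description = "ols oracle",
                       response = "un_gd", per_bw = FALSE,
                       diet_specific = FALSE,
                       terms = c(intercept = unname(coef(ols)[1]),
                                 mun_mgdl = unname(coef(ols)[2])),
                       se = NULL, requires = "mun_mgdl"),
                  class = "coefficient_set")
  tab <- study_table(d)
  rep <- suppressWarnings(assess_bias(tab, eq, weighted = FALSE))
  expect_equal(rep$per_diet$mean_bias, 0, tolerance = 1e-8)
  expect_equal(rep$per_diet$linear_bias, 0, tolerance = 1e-8)
})

test_that("an injected mean bias in one diet is recovered there only", {
  sim <- quick_sim(31, n_studies = c(TMR = 14L, PASTURE = 8L))
  shifted <- inject_bias(sim$table, mean_shift = 20, diet = "PASTURE",
                         eq = "EQ7")
  rep <- assess_bias(shifted, "EQ7")
  pd <- rep$per_diet
  pas <- pd[pd$diet == "PASTURE", ]
  tmr <- pd[pd$diet == "TMR", ]
  expect_lt(abs(pas$mean_bias - 20), 2 * pas$mean_bias_se)
  expect_lt(abs(tmr$mean_bias), 2 * tmr$mean_bias_se)
})

test_that("an injected linear bias is recovered as the regression slope", {
  sim <- quick_sim(32, n_studies = c(TMR = 14L, PASTURE = 8L))
  shifted <- inject_bias(sim$table, linear_coef = 0.2, eq = "EQ7")
  rep <- assess_bias(shifted, "EQ7")
  for (i in seq_len(nrow(rep$per_diet))) {
    expect_lt(abs(rep$per_diet$linear_bias[i] - 0.2),
              2 * rep$per_diet$linear_bias_se[i])
  }
})

test_that("RMSEP decomposes into squared mean bias plus residual variance", {
  sim <- quick_sim(33)
  tab <- sim$table
  rep <- assess_bias(tab, "EQ1")
  r <- un_residuals(tab, "EQ1")
  for (d in levels(tab$diet)) {
    rd <- r[tab$diet == d]
    popvar <- mean((rd - mean(rd))^2)
    rmsep_d <- rep$per_diet$rmsep[rep$per_diet$diet == d]
    expect_equal(rmsep_d^2, mean(rd)^2 + popvar, tolerance = 1e-9)
    # RPE is RMSEP as a percent of that diet subset's observed mean
    expect_equal(rep$per_diet$rpe[rep$per_diet$diet == d],
                 100 * rmsep_d / mean(tab$un_gd[tab$diet == d]),
                 tolerance = 1e-9)
  }
})

test_that("the bias report is invariant to record order", {
  sim <- quick_sim(34)
  tab <- sim$table
  set.seed(9)
  perm <- study_table(as.data.frame(tab)[sample(nrow(tab)), ],
                      require_sem = TRUE)
  a <- assess_bias(tab, "EQ2")
  b <- assess_bias(perm, "EQ2")
  expect_equal(a$per_diet, b$per_diet, tolerance = 1e-6)
  expect_equal(a$interaction_p_mean, b$interaction_p_mean, tolerance = 1e-6)
})

test_that("a single-diet table degrades to a no-interaction model with a warning", {
  sim <- quick_sim(35, n_studies = c(TMR = 10L, PASTURE = 2L))
  tmr_only <- study_table(
    as.data.frame(sim$table)[sim$table$diet == "TMR", ], require_sem = TRUE)
  expect_warning(rep <- assess_bias(tmr_only, "EQ1"), "single diet")
  expect_identical(nrow(rep$per_diet), 1L)
  expect_true(is.na(rep$interaction_p_mean))
})

test_that("bias sign language translates the stored convention", {
  expect_match(describe_mean_bias(-31.4), "over predicted by 31.4")
  expect_match(describe_mean_bias(12), "under predicted by 12")
  expect_match(describe_mean_bias(0), "unbiased")
})

test_that("residual-covariate regression slopes respond only to real structure", {
  sim <- quick_sim(36)
  tab <- sim$table
  row <- residual_covariate_regression(tab, "EQ1", "dmi_kg")
  expect_identical(row$covariate, "dmi_kg")
  expect_true(is.finite(row$slope) && is.finite(row$slope_p))

  # shifting residuals by a constant moves the intercept, not the slope
  shifted <- tab
  shifted$un_gd <- shifted$un_gd + 50
  row2 <- residual_covariate_regression(shifted, "EQ1", "dmi_kg")
  expect_equal(row2$slope, row$slope, tolerance = 1e-6)
  expect_equal(row2$intercept, row$intercept + 50, tolerance = 1e-4)
})

test_that("a covariate unrelated to the residuals has a null slope", {
  # 200 seeded replicates: regression of EQ7 residuals (noise only, no
  # bias injected) on an independent covariate should cover 0 with 2 SE
  # in >= 90% of replicates
  ok <- logical(200)
  for (r in seq_len(200)) {
    sim <- quick_sim(5000 + r, n_studies = c(TMR = 8L, PASTURE = 4L))
    tab <- sim$table
    set.seed(5000 + r)
    tab$noise_cov <- rnorm(nrow(tab), 50, 10)
    row <- residual_covariate_regression(tab, "EQ7", "noise_cov")
    ok[r] <- abs(row$slope) <= 2 * row$slope_se
  }
  expect_gte(mean(ok), 0.9)
})
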