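test_that("inverse-squared-SEm weights are normalized to mean 1", {
  expect_equal(build_weights(c(1, 1, 1)), c(1, 1, 1))
  # sem (1, 2): raw (1, 0.25), mean 0.625 -> (1.6, 0.4)
  expect_equal(build_weights(c(1, 2)), c(1.6, 0.4))
  set.seed(301)
  for (i in 1:20) {
    w <- build_weights(rgamma(sample(3:40, 1), 15, scale = 0.7))
    expect_equal(mean(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_equal(build_weights(NULL, n = 4), rep(1, 4))
  expect_equal(build_weights(rep(NA_real_, 3)), rep(1, 3))
  expect_error(build_weights(c(1, NA, 2)), "partial")
  expect_error(build_weights(c(1, 0)), "> 0")
})

test_that("weights are invariant to rescaling all SEm by a constant", {
  sem <- c(4, 9, 2.5, 7)
  expect_equal(build_weights(sem), build_weights(sem * 17.3))
})

test_that("with var_study fixed at 0 the fit is closed-form weighted least squares", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    d <- data.frame(study_id = sprintf("s%d", sample(1:5, n, replace = TRUE)),
                    x1 = rnorm(n), x2 = runif(n))
    d$y <- 1 + 0.5 * d$x1 - 2 * d$x2 + rnorm(n)
    w <- build_weights(rgamma(n, 20, scale = 0.5))
    f <- fit_wlmm(y ~ x1 + x2, d, weights = w, fix_lambda = 0)
    # oracle: weighted normal equations
    X <- model.matrix(~ x1 + x2, d)
    beta_wls <- solve(t(X) %*% (X * w), t(X) %*% (d$y * w))
    expect_equal(unname(f$coefficients), unname(drop(beta_wls)),
                 tolerance = 1e-8)
    # and the standard WLS fitter agrees on coefficients and SEs
    lmfit <- lm(y ~ x1 + x2, data = d, weights = w)
    expect_equal(f$coefficients, coef(lmfit), tolerance = 1e-8)
    expect_equal(f$coef_se, summary(lmfit)$coefficients[, "Std. Error"],
                 tolerance = 1e-8)
    expect_equal(f$var_study, 0)
  }
})

test_that("the REML fit agrees with the reference mixed-model fitter", {
  skip_if_not_installed("lme4")
  for (seed in c(42, 91, 7)) {
    ed <- make_engine_data(seed)
    f <- fit_wlmm(y ~ x1 + x2, ed$data, weights = ed$weights)
    m <- lme4::lmer(y ~ x1 + x2 + (1 | study_id), data = ed$data,
                    weights = ed$weights, REML = TRUE)
    expect_equal(unname(f$coefficients), unname(lme4::fixef(m)),
                 tolerance = 1e-6)
    expect_equal(unname(f$coef_se),
                 unname(sqrt(diag(as.matrix(vcov(m))))), tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(f$var_study, vc$vcov[1], tolerance = 1e-4)
    expect_equal(f$var_resid, vc$vcov[2], tolerance = 1e-5)
    expect_equal(-2 * f$loglik_reml, lme4::REMLcrit(m), tolerance = 1e-8)
  }
})

test_that("the fit is equivariant under response scaling", {
  ed <- make_engine_data(5)
  f1 <- fit_wlmm(y ~ x1 + x2, ed$data, weights = ed$weights)
  d2 <- ed$data
  k <- 7.3
  d2$y <- d2$y * k
  f2 <- fit_wlmm(y ~ x1 + x2, d2, weights = ed$weights)
  expect_equal(f2$coefficients, f1$coefficients * k, tolerance = 1e-6)
  expect_equal(f2$rsd, f1$rsd * k, tolerance = 1e-6)
  expect_equal(f2$var_study, f1$var_study * k^2, tolerance = 1e-5)
  expect_equal(f2$var_resid, f1$var_resid * k^2, tolerance = 1e-6)
  # variance partition is scale-free
  expect_equal(variance_partition(f2), variance_partition(f1),
               tolerance = 1e-6)
})

test_that("rescaling every SEm leaves the mixed-model fit unchanged", {
  ed <- make_engine_data(8)
  sem <- ed$data$sem
  f1 <- fit_wlmm(y ~ x1 + x2, ed$data, weights = build_weights(sem))
  f2 <- fit_wlmm(y ~ x1 + x2, ed$data, weights = build_weights(sem * 0.31))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$var_study, f2$var_study, tolerance = 1e-6)
})

test_that("one record per study collapses to WLS with a warning", {
  set.seed(12)
  d <- data.frame(study_id = sprintf("s%d", 1:20), x = rnorm(20))
  d$y <- 2 + d$x + rnorm(20)
  expect_warning(f <- fit_wlmm(y ~ x, d), "confounded")
  expect_equal(f$var_study, 0)
  expect_equal(f$var_partition_study_pct, 0)
})

test_that("rank deficiency fails loudly naming the aliased columns", {
  ed <- make_engine_data(3)
  d <- ed$data
  d$x3 <- d$x1 + d$x2
  expect_error(fit_wlmm(y ~ x1 + x2 + x3, d, weights = ed$weights),
               "aliased.*x3")
})

test_that("variance partition arithmetic", {
  fake <- structure(list(var_study = 3, var_resid = 1), class = "wlmm_fit")
  expect_equal(unname(variance_partition(fake)), c(75, 25))
  fake$var_study <- 1
  expect_equal(unname(variance_partition(fake)), c(50, 50))
  fake$var_study <- 0
  expect_equal(unname(variance_partition(fake)), c(0, 100))
  fake$var_resid <- 0
  expect_error(variance_partition(fake), "zero")
  ed <- make_engine_data(21)
  f <- fit_wlmm(y ~ x1, ed$data, weights = ed$weights)
  expect_equal(sum(variance_partition(f)), 100, tolerance = 1e-9)
  expect_equal(f$var_partition_study_pct + f$var_partition_resid_pct, 100,
               tolerance = 1e-9)
})

test_that("Wald t tests behave at the null value and in the strong-signal limit", {
  fake <- structure(list(
    coefficients = c(a = 0, b = 50),
    coef_se = c(a = 2, b = 0.001),
    t_values = c(a = 0, b = 50000),
    p_values = 2 * pt(c(0, 50000), df = 30, lower.tail = FALSE),
    df_denominator = 30), class = "wlmm_fit")
  wt <- wald_tests(fake)
  expect_equal(wt$p[wt$term == "a"], 1)
  expect_lt(wt$p[wt$term == "b"], 1e-12)
  fake$coef_se <- c(a = 0, b = 1)
  expect_error(wald_tests(fake), "zero")
})

test_that("a null covariate is rejected at close to the nominal 5% rate", {
  # 1000 seeded refits of a model with an unrelated covariate z; the
  # rejection rate of its Wald test should sit near alpha = 0.05
  rej <- logical(1000)
  for (r in seq_len(1000)) {
    set.seed(r)
    g <- rep(1:10, each = 4)
    d <- data.frame(study_id = sprintf("s%02d", g),
                    x = rnorm(40, 10, 2), z = rnorm(40))
    u <- rnorm(10, 0, 2)
    d$y <- 3 + 1.5 * d$x + u[g] + rnorm(40, 0, 1.5)
    f <- fit_wlmm(y ~ x + z, d)
    rej[r] <- f$p_values[["z"]] < 0.05
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("coefficients generated under the model are recovered within 2 SE", {
  # Monte-Carlo recovery: simulated grouped data with known fixed effects;
  # each coefficient should be covered by estimate +/- 2 SE in >= 90% of
  # replicates
  n_rep <- 200
  cover <- matrix(NA, n_rep, 3)
  for (r in seq_len(n_rep)) {
    ed <- make_engine_data(1000 + r)
    f <- fit_wlmm(y ~ x1 + x2, ed$data, weights = ed$weights)
    cover[r, ] <- abs(f$coefficients - ed$beta) <= 2 * f$coef_se
  }
  expect_true(all(colMeans(cover) >= 0.9))
})
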