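# Shared fixtures, built in code.

# A small deterministic hand-written table: 4 studies (2 per diet), 10
# treatment means, plausible magnitudes.
make_small_table <- function(require_sem = TRUE) {
  df <- data.frame(
    study_id = c("10.1/a", "10.1/a", "10.1/a",
                 "10.1/b", "10.1/b",
                 "10.2/c", "10.2/c", "10.2/c",
                 "10.2/d", "10.2/d"),
    diet = c(rep("TMR", 5), rep("PASTURE", 5)),
    un_gd = c(190, 205, 178, 210, 188, 230, 215, 241, 198, 224),
    un_sem = c(8, 9, 7.5, 12, 10, 9, 8.5, 11, 10, 9.5),
    mun_mgdl = c(12.1, 13.4, 11.0, 14.2, 12.8, 17.9, 16.5, 19.2, 15.8, 18.4),
    bw_kg = c(640, 640, 640, 655, 655, 505, 505, 505, 515, 515),
    dmi_kg = c(21.5, 22.3, 20.8, 23.0, 21.9, 16.8, 16.1, 17.5, 15.9, 17.0),
    cp_pct = c(16.2, 16.9, 15.8, 17.3, 16.5, 19.1, 18.4, 20.2, 18.0, 19.6),
    stringsAsFactors = FALSE
  )
  if (!require_sem) df$un_sem <- NULL
  study_table(df, provenance = "hand-built test fixture",
              require_sem = require_sem)
}

# Simulated grouped data for engine tests: known fixed effects, one
# random intercept per study, heterogeneous weights.
make_engine_data <- function(seed, n_studies = 12, means = 2:5,
                             beta = c(5, 2, -1.5), sd_u = 2, sd_e = 3) {
  set.seed(seed)
  npg <- sample(means, n_studies, replace = TRUE)
  g <- rep(sprintf("s%02d", seq_len(n_studies)), npg)
  n <- length(g)
  x1 <- rnorm(n, 10, 3)
  x2 <- rnorm(n, 17, 2)
  sem <- rgamma(n, 20, scale = 0.5)
  w <- build_weights(sem)
  u <- rnorm(n_studies, 0, sd_u)
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 +
    u[as.integer(factor(g))] + rnorm(n, 0, sd_e) / sqrt(w)
  list(data = data.frame(study_id = g, y = y, x1 = x1, x2 = x2, sem = sem),
       weights = w, beta = beta)
}

# Drop the provenance note so content comparisons ignore metadata.
strip_prov <- function(df) {
  df <- as.data.frame(df)
  attr(df, "provenance") <- NULL
  df
}

# A quick small simulation config for pipeline-level tests.
quick_sim <- function(seed, n_studies = c(TMR = 10L, PASTURE = 6L), ...) {
  simulate_study_table(sim_config(seed = seed, n_studies = n_studies, ...))
}
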