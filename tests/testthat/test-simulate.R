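test_that("generation is deterministic under a seed", {
  c1 <- simulate_model_mode(simulation_config(n = 200, seed = 7))
  c2 <- simulate_model_mode(simulation_config(n = 200, seed = 7))
  expect_identical(c1, c2)
  c3 <- simulate_model_mode(simulation_config(n = 200, seed = 8))
  expect_false(identical(c1, c3))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(n = 0), "'n'")
  expect_error(simulation_config(n = 10, p_female = 1.2), "'p_female'")
  expect_error(simulation_config(n = 10, bw_z_sd = -1), "'bw_z_sd'")
  expect_error(simulation_config(n = 10, education_probs = c(1, 0)),
               "'education_probs'")
})

test_that("sample moments converge to the configured moments", {
  cfg <- simulation_config(n = 1e5, seed = 12)
  d <- simulate_model_mode(cfg)
  n <- nrow(d)
  tol3 <- function(sd) 3 * sd / sqrt(n)
  expect_lt(abs(mean(d$bw_z) - -0.56), tol3(1.2))
  expect_lt(abs(stats::sd(d$bw_z) - 1.2), 0.02)
  expect_lt(abs(mean(d$gain_z)), tol3(1))
  expect_lt(abs(stats::sd(d$gain_z) - 1), 0.02)
  expect_lt(abs(mean(d$sex == "female") - 0.49), tol3(0.5))
  expect_lt(abs(mean(d$ethnicity == "south_asian") - 0.52), tol3(0.5))
  expect_lt(abs(mean(d$smoked) - 0.13), tol3(0.35))
  # maternal BMI is truncated to [13, 60]: compare to the truncated mean
  a <- (13 - 25.9) / 5.6; b <- (60 - 25.9) / 5.6
  mu_trunc <- 25.9 + 5.6 * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
  expect_lt(abs(mean(d$maternal_bmi) - mu_trunc), tol3(5.6))
  expect_true(all(d$maternal_bmi >= 13 & d$maternal_bmi <= 60))
  # conditional gain independent of birthweight z by construction
  expect_lt(abs(stats::cor(d$bw_z, d$gain_z)), 0.015)
})

test_that("outcome prevalence is emergent and in the plausible band", {
  d <- simulate_model_mode(bib_preset("eq3", n = 5e4, seed = 4))
  expect_gt(mean(d$outcome), 0.05)
  expect_lt(mean(d$outcome), 0.11)
  # null model: everything 0 gives 50%
  null_spec <- equation_spec("eq1", "base", alpha = 0, beta_female = 0,
                             beta_bw_z = 0, beta_gain_z = 0,
                             t10 = 0.3, t20 = 0.2, t30 = 0.1)
  d0 <- simulate_model_mode(simulation_config(n = 2e4, seed = 5,
                                              spec = null_spec))
  expect_equal(mean(d0$outcome), 0.5, tolerance = 0.015)
})

test_that("the external preset carries the leaner validation-sample profile", {
  cfg <- external_preset(n = 5e4, seed = 6)
  expect_equal(cfg$maternal_bmi_mean, 23.4)
  expect_equal(cfg$maternal_bmi_sd, 4.0)
  d <- simulate_model_mode(cfg)
  expect_lt(abs(mean(d$maternal_bmi) - 23.4), 3 * 4 / sqrt(5e4) + 0.01)
  expect_lt(abs(mean(d$ethnicity == "south_asian") - 0.017), 0.005)
  # prevalence close to the ~9.6-9.7% seen in the validation samples
  expect_gt(mean(d$outcome), 0.06)
  expect_lt(mean(d$outcome), 0.13)
})

test_that("model-mode cohorts refit to the generating coefficients", {
  d <- simulate_model_mode(simulation_config(n = 1e5, seed = 14,
                                             spec = published_equations()$eq1))
  res <- backward_stepwise(d, c("sex", "bw_z", "gain_z"), forced = "sex")
  expect_lt(abs(res$coefficients[["sexfemale"]] - 0.488),
            3 * res$se[["sexfemale"]])
  expect_lt(abs(res$coefficients[["bw_z"]] - 0.599), 3 * res$se[["bw_z"]])
  expect_lt(abs(res$coefficients[["gain_z"]] - 1.501),
            3 * res$se[["gain_z"]])
})

test_that("growth mode round-trips raw measurements through the reference", {
  g <- simulate_growth_mode(simulation_config(n = 500, seed = 15,
                                              mode = "growth"), test_refs)
  m <- g$measurements
  expect_equal(nrow(m), 3 * 500)
  # z-scoring the emitted weights recovers the latent z to 1e-6
  birth <- m[m$age_days == 0, ]
  for (s in c("male", "female")) {
    i <- birth$sex == s
    z <- lms_zscore(birth$weight_kg[i], 0, s, test_refs, "weight")
    expect_equal(z, g$latent$zb[i], tolerance = 1e-6)
  }
  two_y <- m[m$age_days >= 669 & !is.na(m$length_cm), ]
  for (s in c("male", "female")) {
    i <- two_y$sex == s
    bmi <- two_y$weight_kg[i] / (two_y$length_cm[i] / 100)^2
    z <- lms_zscore(bmi, two_y$age_days[i], s, test_refs, "bmi")
    expect_equal(z, g$latent$zbmi[i], tolerance = 1e-6)
  }
  # outcomes satisfy the composite rule exactly
  cg <- conditional_gain_z(g$latent$zb, g$latent$z2, g$conditional_2y)
  expect_identical(g$cohort$outcome,
                   as.integer(outcome_flag(g$latent$zbmi, cg)))
})

test_that("growth mode recovers the latent conditioning slope", {
  g <- simulate_growth_mode(simulation_config(n = 1e4, seed = 16,
                                              mode = "growth",
                                              r_birth_assess = 0.5),
                            test_refs)
  # slope of assessment z on standardized birth z: r / bw_z_sd
  expect_lt(abs(g$conditional_assess$b - 0.5 / 1.2), 0.025)
  # gains in the fitting sample are standardized
  expect_lt(abs(mean(g$cohort$gain_z)), 1e-9)
})

test_that("a median cohort yields median weights and zero prevalence", {
  cfg <- simulation_config(n = 50, seed = 18, mode = "growth",
                           bw_z_mean = 0, bw_z_sd = 1e-7,
                           r_birth_assess = 0, r_birth_2y = 0,
                           r_assess_2y = 0, r_bmi_weight_2y = 0,
                           bmi_z_2y_sd = 1e-7)
  # shrink all latent variation: every z ~ 0
  cfg$r_birth_assess <- 0; cfg$r_assess_2y <- 0
  g <- simulate_growth_mode(cfg, test_refs)
  expect_equal(mean(g$cohort$outcome), 0)
  birth <- g$measurements[g$measurements$age_days == 0, ]
  med <- vapply(seq_len(nrow(birth)), function(i)
    lms_value_for_z(0, 0, birth$sex[i], test_refs, "weight"), numeric(1))
  expect_equal(birth$weight_kg, med, tolerance = 1e-5)
})
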