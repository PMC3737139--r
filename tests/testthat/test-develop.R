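test_that("fit_logistic reproduces the saturated 2x2 log odds ratio", {
  # exposed: 10 events / 90 non-events; unexposed: 5 / 95
  x <- rep(c(1, 0), c(100, 100))
  y <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  fit <- fit_logistic(y, cbind(1, x))
  expect_equal(unname(fit$coefficients[2]), log(10 * 95 / (90 * 5)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[1]), log(5 / 95), tolerance = 1e-8)
  expect_lt(fit$gradient_norm, 1e-8)
})

test_that("a balanced fully crossed design gives zero coefficients", {
  x <- rep(c(0, 0, 1, 1), each = 25)
  y <- rep(c(0, 1, 0, 1), each = 25)
  fit <- fit_logistic(y, cbind(1, x))
  expect_equal(unname(fit$coefficients), c(0, 0), tolerance = 1e-10)
})

test_that("separation and degenerate designs raise explicit errors", {
  x <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(x, cbind(1, x)), "separation")
  expect_error(fit_logistic(x, cbind(1, rep(2, 40))), "constant column")
  expect_error(fit_logistic(rep(1, 40), cbind(1, rnorm(40))), "single class")
  expect_error(fit_logistic(x, cbind(1, x, x)), "rank deficient")
})

test_that("fit_logistic agrees with glm and with grid maximization", {
  set.seed(5)
  x <- stats::rnorm(200)
  y <- stats::rbinom(200, 1, stats::plogis(-0.5 + 0.8 * x))
  fit <- fit_logistic(y, cbind(`(Intercept)` = 1, x = x))
  ref <- stats::glm(y ~ x, family = stats::binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)

  # brute-force grid maximization of the log-likelihood, refined twice
  loglik_grid <- function(as, bs) {
    best <- c(NA, NA); best_ll <- -Inf
    for (a in as) {
      lp <- a + outer(bs, x)
      lls <- drop(lp %*% y) - rowSums(log1p(exp(lp)))
      k <- which.max(lls)
      if (lls[k] > best_ll) { best_ll <- lls[k]; best <- c(a, bs[k]) }
    }
    best
  }
  coarse <- loglik_grid(seq(-2, 1, by = 0.05), seq(-1, 2, by = 0.05))
  fine <- loglik_grid(seq(coarse[1] - 0.05, coarse[1] + 0.05, by = 1e-3),
                      seq(coarse[2] - 0.05, coarse[2] + 0.05, by = 1e-3))
  finest <- loglik_grid(seq(fine[1] - 1e-3, fine[1] + 1e-3, by = 5e-5),
                        seq(fine[2] - 1e-3, fine[2] + 1e-3, by = 5e-5))
  expect_equal(unname(fit$coefficients), finest, tolerance = 1e-4)
})

test_that("stepwise keeps true predictors and drops a pure-noise covariate", {
  set.seed(31)
  cohort <- simulate_model_mode(simulation_config(
    n = 20000, seed = 31, spec = published_equations()$eq3))
  cohort$noise <- stats::rnorm(nrow(cohort))
  res <- backward_stepwise(cohort, c("sex", "bw_z", "gain_z", "noise"))
  expect_true(all(c("bw_z", "gain_z") %in% res$terms))
  expect_false("noise" %in% res$terms)
  expect_equal(unname(res$coefficients["bw_z"]), 0.824, tolerance = 0.1)
  expect_equal(unname(res$coefficients["gain_z"]), 2.174, tolerance = 0.12)
})

test_that("all-noise candidates are retained at about the nominal 5% rate", {
  set.seed(17)
  retained <- logical(200)
  for (i in seq_len(200)) {
    x <- stats::rnorm(300)
    y <- stats::rbinom(300, 1, 0.3)
    cohort <- data.frame(noise = x, outcome = y)
    res <- backward_stepwise(cohort, "noise")
    retained[i] <- "noise" %in% res$terms
  }
  # binomial(200, 0.05): mean 10, 3 SE ~ 9.3
  expect_lt(mean(retained), 0.10)
})

test_that("duplicated covariates are repaired without changing the fit", {
  cohort <- small_cohort(2000)
  cohort$bw_copy <- cohort$bw_z
  res <- backward_stepwise(cohort, c("sex", "bw_z", "gain_z", "bw_copy"))
  expect_equal(res$dropped_rank_deficient, "bw_copy")  # later term removed
  ref <- backward_stepwise(cohort, c("sex", "bw_z", "gain_z"))
  expect_equal(res$deviance, ref$deviance)
})

test_that("interaction hierarchy is respected during removal", {
  # a term's main effects stay while the interaction is in the model, and a
  # main effect can only be removed after its interaction
  for (seed in c(41, 43, 47)) {
    cohort <- small_cohort(3000, seed = seed)
    res <- backward_stepwise(cohort, c("sex", "bw_z", "gain_z", "ethnicity"),
                             interactions = c("sex:bw_z", "ethnicity:gain_z"),
                             forced = "sex")
    expect_true(all(c("sex", "bw_z", "gain_z") %in% res$terms))
    for (int in c("sex:bw_z", "ethnicity:gain_z")) {
      mains <- strsplit(int, ":")[[1]]
      if (int %in% res$terms) {
        # retained interaction keeps its main effects in the model
        expect_true(all(mains %in% res$terms))
      } else {
        for (mn in intersect(mains, res$removed))
          expect_lt(match(int, res$removed), match(mn, res$removed))
      }
    }
  }
})

test_that("education enters and leaves as a block", {
  cohort <- small_cohort(3000, seed = 9)
  res <- backward_stepwise(cohort, c("sex", "bw_z", "gain_z", "education"))
  # either all four dummies present or none
  n_dummies <- sum(grepl("^education", names(res$coefficients)))
  expect_true(n_dummies %in% c(0L, 4L))
  expect_false("education" %in% res$terms)  # null effect in this DGP
})

test_that("deviance never increases when a term is added", {
  cohort <- small_cohort(2000, seed = 13)
  terms <- c("sex", "bw_z", "gain_z", "maternal_bmi", "smoked")
  dev <- vapply(seq_along(terms), function(k) {
    backward_stepwise(cohort, terms[seq_len(k)], alpha = 1,
                      forced = terms[seq_len(k)])$deviance
  }, numeric(1))
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("odds-ratio tables are exp(b) with 1.959964 SE intervals", {
  res <- list(coefficients = c(`(Intercept)` = -2, x = 0, w = -1.347),
              se = c(`(Intercept)` = 0.2, x = 0.3, w = 0.665))
  tab <- development_ors(res)
  expect_equal(unname(tab["x", "or"]), 1)
  expect_equal(round(unname(tab["w", c("ci_lo", "ci_hi")]), 2),
               c(0.07, 0.96))
  expect_equal(round(exp(0.824), 2), 2.28)
})
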