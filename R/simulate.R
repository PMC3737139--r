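#' Configuration for synthetic-cohort generation
#'
#' Collects the sampling parameters for a seeded synthetic cohort. The
#' defaults emulate the development sample of the 6-month (eq1) equation:
#' birthweight z mean -0.56 (SD 1.2), conditional gain z mean 0 (SD 1,
#' independent of birthweight z by construction of the conditioning
#' residual), maternal BMI 25.9 (SD 5.6, truncated to 13-60 kg/m^2),
#' 49% female, 52% South Asian, 13% smoked in pregnancy, 7.4% gestational
#' diabetes, 4.6% preterm. Outcome prevalence is emergent, not forced: in
#' model mode it follows from `spec`'s intercept and the covariate
#' distribution.
#'
#' @param n number of records
#' @param seed optional integer seed (set before any draws)
#' @param mode `"model"` (outcome drawn from the logistic model) or
#'   `"growth"` (raw measurements drawn from the LMS reference, outcome from
#'   the composite rule)
#' @param p_female,p_south_asian,p_smoked,p_gdm,p_preterm probabilities
#' @param bw_z_mean,bw_z_sd,gain_z_mean,gain_z_sd,maternal_bmi_mean,maternal_bmi_sd
#'   covariate moments
#' @param bmi_z_2y_mean,bmi_z_2y_sd moments of the 2-year BMI z-score
#' @param education_probs multinomial probabilities over the five education
#'   levels (below 5 GCSEs, 5+ GCSEs, A-level, degree, other)
#' @param spec the [equation_spec()] acting as the data-generating model in
#'   model mode
#' @param outcome_rule the [outcome_rule()] for growth mode
#' @param assess_window_days growth mode: range the assessment age is drawn
#'   uniformly from (default the 6-month window)
#' @param followup_window_days growth mode: range of the 2-year
#'   measurement age (default 730 +/- 61 days)
#' @param r_birth_assess,r_birth_2y,r_assess_2y growth mode: latent
#'   correlations between the standardized weight z process at birth,
#'   assessment and 2 years
#' @param r_bmi_weight_2y growth mode: correlation of 2-year BMI z with
#'   2-year weight z
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(n, seed = NULL, mode = c("model", "growth"),
                              p_female = 0.49,
                              bw_z_mean = -0.56, bw_z_sd = 1.2,
                              gain_z_mean = 0, gain_z_sd = 1,
                              maternal_bmi_mean = 25.9,
                              maternal_bmi_sd = 5.6,
                              p_south_asian = 0.52, p_smoked = 0.13,
                              p_gdm = 0.074, p_preterm = 0.046,
                              bmi_z_2y_mean = -0.05, bmi_z_2y_sd = 1.15,
                              education_probs =
                                c(0.186, 0.303, 0.168, 0.285, 0.058),
                              spec = published_equations()$eq1,
                              outcome_rule = NULL,
                              assess_window_days = c(137, 228),
                              followup_window_days = c(669, 791),
                              r_birth_assess = 0.5, r_birth_2y = 0.45,
                              r_assess_2y = 0.75, r_bmi_weight_2y = 0.8) {
  mode <- match.arg(mode)
  if (is.null(outcome_rule)) outcome_rule <- growthrisk::outcome_rule()
  cfg <- list(n = n, seed = seed, mode = mode, p_female = p_female,
              bw_z_mean = bw_z_mean, bw_z_sd = bw_z_sd,
              gain_z_mean = gain_z_mean, gain_z_sd = gain_z_sd,
              maternal_bmi_mean = maternal_bmi_mean,
              maternal_bmi_sd = maternal_bmi_sd,
              p_south_asian = p_south_asian, p_smoked = p_smoked,
              p_gdm = p_gdm, p_preterm = p_preterm,
              bmi_z_2y_mean = bmi_z_2y_mean, bmi_z_2y_sd = bmi_z_2y_sd,
              education_probs = education_probs, spec = spec,
              outcome_rule = outcome_rule,
              assess_window_days = assess_window_days,
              followup_window_days = followup_window_days,
              r_birth_assess = r_birth_assess, r_birth_2y = r_birth_2y,
              r_assess_2y = r_assess_2y,
              r_bmi_weight_2y = r_bmi_weight_2y)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || cfg$n < 1)
    stop("invalid config field 'n': need n >= 1")
  for (f in c("p_female", "p_south_asian", "p_smoked", "p_gdm", "p_preterm"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config field '", f, "': must be a probability in [0, 1]")
  for (f in c("bw_z_sd", "gain_z_sd", "maternal_bmi_sd", "bmi_z_2y_sd"))
    if (cfg[[f]] <= 0)
      stop("invalid config field '", f, "': must be positive")
  if (length(cfg$education_probs) != 5L ||
      any(cfg$education_probs < 0) || sum(cfg$education_probs) <= 0 ||
      abs(sum(cfg$education_probs) - 1) > 0.02)
    stop("invalid config field 'education_probs': 5 non-negative values summing to ~1")
  if (!inherits(cfg$spec, "equation_spec"))
    stop("invalid config field 'spec': need an equation_spec")
  invisible(cfg)
}

# maternal BMI: truncated normal on [13, 60] kg/m^2 by rejection, so draws
# stay physiologically plausible without distorting the central shape
rtrunc_bmi <- function(n, mean, sd, lo = 13, hi = 60) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

draw_covariates <- function(cfg) {
  n <- cfg$n
  data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = ifelse(stats::rbinom(n, 1, cfg$p_female) == 1, "female", "male"),
    ethnicity = ifelse(stats::rbinom(n, 1, cfg$p_south_asian) == 1,
                       "south_asian", "white_british"),
    bw_z = stats::rnorm(n, cfg$bw_z_mean, cfg$bw_z_sd),
    gain_z = stats::rnorm(n, cfg$gain_z_mean, cfg$gain_z_sd),
    maternal_bmi = rtrunc_bmi(n, cfg$maternal_bmi_mean, cfg$maternal_bmi_sd),
    education = sample(EDUCATION_LEVELS, n, replace = TRUE,
                       prob = cfg$education_probs),
    smoked = stats::rbinom(n, 1, cfg$p_smoked),
    gdm = stats::rbinom(n, 1, cfg$p_gdm),
    preterm = stats::rbinom(n, 1, cfg$p_preterm),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort from the logistic risk model
#'
#' Model mode: covariates are drawn independently (conditional gain is
#' independent of birthweight z by construction of the conditioning
#' residual) and the outcome is Bernoulli with probability given by the
#' configured equation's logistic model. The 2-year BMI z-score column is
#' filled with draws from its marginal distribution: in model mode the
#' outcome is defined by the model, not by the composite rule.
#'
#' @param config a [simulation_config()] with `mode = "model"`
#' @return a cohort data frame (one row per infant, columns as in
#'   [read_cohort()])
#' @export
#' @examples
#' cfg <- simulation_config(n = 1000, seed = 1)
#' cohort <- simulate_model_mode(cfg)
#' mean(cohort$outcome)  # emergent prevalence, ~7-8%
simulate_model_mode <- function(config) {
  validate_simulation_config(config)
  if (config$mode != "model") stop("config mode must be 'model'")
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- draw_covariates(config)
  d$bmi_z_2y <- stats::rnorm(config$n, config$bmi_z_2y_mean,
                             config$bmi_z_2y_sd)
  p <- predict_probability(
    d$sex, d$bw_z, d$gain_z, config$spec,
    maternal_bmi = if (config$spec$variant == "with_maternal_bmi")
      d$maternal_bmi else NULL)
  d$outcome <- stats::rbinom(config$n, 1, p)
  d[COHORT_COLUMNS]
}

#' Simulate raw growth measurements and the derived cohort
#'
#' Growth mode exercises the full raw-measurement path. A latent
#' standardized weight z process at birth, assessment age and 2 years is
#' drawn from a trivariate normal with the configured correlations (plus a
#' 2-year BMI z correlated with 2-year weight z), then inverted through the
#' LMS reference to raw weights; the 2-year length is set so that the
#' emitted weight and length reproduce the latent BMI z. Outcomes are
#' computed by [outcome_flag()] from the composite rule, not drawn from a
#' logistic model, and the conditioning regressions are fitted within the
#' generated cohort.
#'
#' @param config a [simulation_config()] with `mode = "growth"`
#' @param refs an `lms_reference_set` spanning 0 to ~30 months
#' @return a list: `measurements` (long data frame: subject_id, sex,
#'   age_days, weight_kg, length_cm), `cohort` (the derived cohort table),
#'   `conditional_assess` and `conditional_2y` (the fitted
#'   [conditional_model]s), `latent` (the latent z draws)
#' @export
simulate_growth_mode <- function(config, refs) {
  validate_simulation_config(config)
  if (config$mode != "growth") stop("config mode must be 'growth'")
  stopifnot(inherits(refs, "lms_reference_set"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  d <- draw_covariates(config)

  C <- matrix(c(1, config$r_birth_assess, config$r_birth_2y,
                config$r_birth_assess, 1, config$r_assess_2y,
                config$r_birth_2y, config$r_assess_2y, 1), 3, 3)
  U <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(C)
  zb <- config$bw_z_mean + config$bw_z_sd * U[, 1]
  za <- U[, 2]
  z2 <- U[, 3]
  r <- config$r_bmi_weight_2y
  zbmi <- config$bmi_z_2y_mean +
    config$bmi_z_2y_sd * (r * z2 + sqrt(1 - r^2) * stats::rnorm(n))

  age_a <- sample(seq(config$assess_window_days[1],
                      config$assess_window_days[2]), n, replace = TRUE)
  age_2 <- sample(seq(config$followup_window_days[1],
                      config$followup_window_days[2]), n, replace = TRUE)

  inv <- function(z, age, measurement) {
    out <- numeric(n)
    for (s in c("male", "female")) {
      i <- d$sex == s
      if (any(i)) out[i] <- lms_value_for_z(z[i], age[i], s, refs, measurement)
    }
    out
  }
  w0 <- inv(zb, rep(0, n), "weight")
  wa <- inv(za, age_a, "weight")
  w2 <- inv(z2, age_2, "weight")
  bmi2 <- inv(zbmi, age_2, "bmi")
  len2 <- 100 * sqrt(w2 / bmi2)

  measurements <- rbind(
    data.frame(subject_id = d$subject_id, sex = d$sex, age_days = 0L,
               weight_kg = w0, length_cm = NA_real_),
    data.frame(subject_id = d$subject_id, sex = d$sex, age_days = age_a,
               weight_kg = wa, length_cm = NA_real_),
    data.frame(subject_id = d$subject_id, sex = d$sex, age_days = age_2,
               weight_kg = w2, length_cm = len2))

  cm_assess <- fit_conditional_model(zb, za, 0L, as.integer(mean(age_a)))
  cm_2y <- fit_conditional_model(zb, z2, 0L, as.integer(mean(age_2)))
  d$bw_z <- zb
  d$gain_z <- conditional_gain_z(zb, za, cm_assess)
  d$bmi_z_2y <- zbmi
  cg_2y <- conditional_gain_z(zb, z2, cm_2y)
  d$outcome <- as.integer(outcome_flag(zbmi, cg_2y, config$outcome_rule))

  list(measurements = measurements, cohort = d[COHORT_COLUMNS],
       conditional_assess = cm_assess, conditional_2y = cm_2y,
       latent = data.frame(zb = zb, za = za, z2 = z2, zbmi = zbmi,
                           age_assess = age_a, age_2y = age_2))
}

#' Preset configurations for the development samples
#'
#' `bib_preset()` returns a [simulation_config()] with the covariate moments
#' of the named development-equation sample (per-equation sex split,
#' birthweight z, maternal BMI, ethnicity, education and risk-factor rates);
#' the generating model is the published equation for that window.
#' `external_preset()` emulates the external validation sample: almost
#' entirely White, leaner mothers (BMI 23.4, SD 4.0), birthweight z near 0,
#' scored/generated with the 12-month equation by default.
#'
#' @param equation `"eq1"`, `"eq2"` or `"eq3"`
#' @param variant `"base"` or `"with_maternal_bmi"`
#' @param n,seed passed to [simulation_config()]
#' @param ... further overrides passed to [simulation_config()]
#' @return a `simulation_config`
#' @export
bib_preset <- function(equation = c("eq1", "eq2", "eq3"),
                       variant = c("base", "with_maternal_bmi"),
                       n = 1000, seed = NULL, ...) {
  equation <- match.arg(equation)
  variant <- match.arg(variant)
  key <- if (variant == "base") equation else paste0(equation, "_mbmi")
  par <- switch(equation,
    eq1 = list(p_female = 0.474, bw_z_mean = -0.56, maternal_bmi_mean = 25.9,
               maternal_bmi_sd = 5.6, p_south_asian = 0.519,
               p_smoked = 0.133, p_gdm = 0.074, p_preterm = 0.046,
               education_probs = c(0.186, 0.303, 0.168, 0.285, 0.058),
               assess_window_days = c(137, 228)),
    eq2 = list(p_female = 0.486, bw_z_mean = -0.54, maternal_bmi_mean = 26.0,
               maternal_bmi_sd = 5.6, p_south_asian = 0.572,
               p_smoked = 0.132, p_gdm = 0.074, p_preterm = 0.049,
               education_probs = c(0.216, 0.309, 0.153, 0.266, 0.057),
               assess_window_days = c(229, 319)),
    eq3 = list(p_female = 0.497, bw_z_mean = -0.58, maternal_bmi_mean = 25.8,
               maternal_bmi_sd = 5.5, p_south_asian = 0.547,
               p_smoked = 0.133, p_gdm = 0.079, p_preterm = 0.045,
               education_probs = c(0.194, 0.304, 0.170, 0.267, 0.066),
               assess_window_days = c(320, 410)))
  args <- c(list(n = n, seed = seed, spec = published_equations()[[key]]),
            par, list(...))
  do.call(simulation_config, args[!duplicated(names(args))])
}

#' @rdname bib_preset
#' @export
external_preset <- function(n = 1000, seed = NULL, ...) {
  args <- c(list(n = n, seed = seed,
                 p_female = 0.458, bw_z_mean = -0.06, bw_z_sd = 1.04,
                 maternal_bmi_mean = 23.4, maternal_bmi_sd = 4.0,
                 p_south_asian = 0.017,   # "non-White" share of the sample
                 p_smoked = 0.168, p_gdm = 0.002, p_preterm = 0.04,
                 bmi_z_2y_mean = 0.21, bmi_z_2y_sd = 0.96,
                 education_probs = c(0.105, 0.367, 0.272, 0.150, 0.106),
                 spec = published_equations()$eq3,
                 assess_window_days = c(320, 410)),
            list(...))
  do.call(simulation_config, args[!duplicated(names(args))])
}
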