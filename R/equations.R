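#' Construct a risk-equation specification
#'
#' One logistic childhood-obesity risk equation: an age window in months, a
#' variant (`"base"` uses sex, birthweight z and conditional weight-gain z;
#' `"with_maternal_bmi"` adds maternal BMI in kg/m^2), the intercept and
#' coefficient vector, and the three score-distribution thresholds used for
#' banding (the score values above which 10%, 20% and 30% of the development
#' population fall).
#'
#' @param id `"eq1"`, `"eq2"` or `"eq3"` (6, 9 and 12 month windows)
#' @param variant `"base"` or `"with_maternal_bmi"`
#' @param alpha intercept (log-odds)
#' @param beta_female coefficient for female sex
#' @param beta_bw_z coefficient for birthweight z-score
#' @param beta_gain_z coefficient for conditional weight-gain z-score
#' @param beta_maternal_bmi coefficient for maternal BMI (required for the
#'   `with_maternal_bmi` variant)
#' @param t10,t20,t30 score thresholds above which 10/20/30% of the
#'   development population fall; must satisfy `t10 > t20 > t30`
#' @return an object of class `equation_spec`
#' @seealso [published_equations()], [predict_probability()]
#' @export
equation_spec <- function(id, variant = c("base", "with_maternal_bmi"),
                          alpha, beta_female, beta_bw_z, beta_gain_z,
                          beta_maternal_bmi = NULL, t10, t20, t30) {
  id <- match.arg(id, c("eq1", "eq2", "eq3"))
  variant <- match.arg(variant)
  if (variant == "with_maternal_bmi" && is.null(beta_maternal_bmi))
    stop("the with_maternal_bmi variant requires beta_maternal_bmi")
  if (variant == "base") beta_maternal_bmi <- NULL
  thr <- c(t10, t20, t30)
  if (any(thr <= 0) || any(thr >= 1))
    stop("thresholds must be probabilities in (0, 1)")
  if (!(t10 > t20 && t20 > t30))
    stop("thresholds must satisfy t10 > t20 > t30")
  windows <- list(eq1 = c(4.5, 7.5), eq2 = c(7.5, 10.5), eq3 = c(10.5, 13.5))
  structure(
    list(id = id, variant = variant, window_months = windows[[id]],
         alpha = alpha, beta_female = beta_female, beta_bw_z = beta_bw_z,
         beta_gain_z = beta_gain_z, beta_maternal_bmi = beta_maternal_bmi,
         thresholds = c(t10 = t10, t20 = t20, t30 = t30)),
    class = "equation_spec")
}

#' @export
print.equation_spec <- function(x, ...) {
  cat(sprintf("<equation_spec> %s (%s), window [%.1f, %.1f) months\n",
              x$id, x$variant, x$window_months[1], x$window_months[2]))
  cat(sprintf("  logit(p) = %.3f + %.3f female + %.3f bw_z + %.3f gain_z%s\n",
              x$alpha, x$beta_female, x$beta_bw_z, x$beta_gain_z,
              if (!is.null(x$beta_maternal_bmi))
                sprintf(" + %.3f maternal_bmi", x$beta_maternal_bmi) else ""))
  cat(sprintf("  band thresholds: t10 = %.4f, t20 = %.4f, t30 = %.4f\n",
              x$thresholds["t10"], x$thresholds["t20"], x$thresholds["t30"]))
  invisible(x)
}

#' The six published risk equations
#'
#' The logistic scoring equations embedded in the scoring engine: one base
#' and one maternal-BMI variant at each of the three assessment windows
#' (6 +/- 1.5, 9 +/- 1.5, 12 +/- 1.5 months), with their development-sample
#' score-distribution thresholds. These are fixed constants from the source
#' development work, not refitted at run time.
#'
#' @return a named list of six [equation_spec()] objects, keyed
#'   `"eq1"`, `"eq2"`, `"eq3"`, `"eq1_mbmi"`, `"eq2_mbmi"`, `"eq3_mbmi"`
#' @export
#' @examples
#' eqs <- published_equations()
#' eqs$eq3$beta_gain_z  # 2.174
published_equations <- function() {
  list(
    eq1 = equation_spec("eq1", "base", alpha = -3.718, beta_female = 0.488,
                        beta_bw_z = 0.599, beta_gain_z = 1.501,
                        t10 = 0.2072, t20 = 0.1155, t30 = 0.0731),
    eq2 = equation_spec("eq2", "base", alpha = -3.542, beta_female = 0.288,
                        beta_bw_z = 0.551, beta_gain_z = 1.508,
                        t10 = 0.2082, t20 = 0.1104, t30 = 0.0662),
    eq3 = equation_spec("eq3", "base", alpha = -3.937, beta_female = 0.234,
                        beta_bw_z = 0.824, beta_gain_z = 2.174,
                        t10 = 0.2391, t20 = 0.1065, t30 = 0.0609),
    eq1_mbmi = equation_spec("eq1", "with_maternal_bmi", alpha = -4.920,
                             beta_female = 0.493, beta_bw_z = 0.577,
                             beta_gain_z = 1.494, beta_maternal_bmi = 0.044,
                             t10 = 0.2183, t20 = 0.1156, t30 = 0.0696),
    eq2_mbmi = equation_spec("eq2", "with_maternal_bmi", alpha = -4.745,
                             beta_female = 0.255, beta_bw_z = 0.505,
                             beta_gain_z = 1.501, beta_maternal_bmi = 0.046,
                             t10 = 0.2042, t20 = 0.1076, t30 = 0.0646),
    eq3_mbmi = equation_spec("eq3", "with_maternal_bmi", alpha = -4.625,
                             beta_female = 0.230, beta_bw_z = 0.798,
                             beta_gain_z = 2.149, beta_maternal_bmi = 0.026,
                             t10 = 0.2404, t20 = 0.1051, t30 = 0.0612))
}

#' Select the risk equation for an assessment age
#'
#' The three windows are half-open on the right except the last:
#' `[4.5, 7.5)` months maps to eq1, `[7.5, 10.5)` to eq2 and `[10.5, 13.5]`
#' to eq3, with months defined as days / 30.4375. Ages outside 4.5-13.5
#' months are an error: the tool is designed for that span of infancy.
#'
#' @param age_days assessment age in days
#' @return `"eq1"`, `"eq2"` or `"eq3"`
#' @export
#' @examples
#' select_equation(183)  # ~6.0 months -> "eq1"
select_equation <- function(age_days) {
  m <- age_days_to_months(age_days)
  if (m < 4.5 || m > 13.5)
    stop(sprintf(
      "assessment age %.1f months (%s days) is outside the supported 4.5-13.5 month range",
      m, age_days))
  if (m < 7.5) "eq1" else if (m < 10.5) "eq2" else "eq3"
}

#' Risk probability from an equation
#'
#' Evaluates the logistic model
#' `p = plogis(alpha + beta_female * [female] + beta_bw_z * bw_z +
#' beta_gain_z * gain_z (+ beta_maternal_bmi * maternal_bmi))`.
#'
#' @param sex `"male"` or `"female"`
#' @param bw_z birthweight z-score
#' @param gain_z conditional weight z-score gain from birth to assessment age
#' @param spec an [equation_spec()]
#' @param maternal_bmi maternal BMI in kg/m^2; required by the
#'   `with_maternal_bmi` variant
#' @return probability in (0, 1)
#' @export
#' @examples
#' eqs <- published_equations()
#' predict_probability("male", bw_z = 0, gain_z = 0, spec = eqs$eq1) # 0.0237
predict_probability <- function(sex, bw_z, gain_z, spec,
                                maternal_bmi = NULL) {
  stopifnot(inherits(spec, "equation_spec"))
  sex <- match_sex(sex)
  if (any(!is.finite(bw_z)) || any(!is.finite(gain_z)))
    stop("bw_z and gain_z must be finite")
  lp <- spec$alpha + spec$beta_female * (sex == "female") +
    spec$beta_bw_z * bw_z + spec$beta_gain_z * gain_z
  if (spec$variant == "with_maternal_bmi") {
    if (is.null(maternal_bmi))
      stop(sprintf("equation %s (with_maternal_bmi) requires maternal_bmi",
                   spec$id))
    if (any(!is.finite(maternal_bmi)) || any(maternal_bmi <= 0))
      stop("maternal_bmi must be positive and finite")
    lp <- lp + spec$beta_maternal_bmi * maternal_bmi
  }
  stats::plogis(lp)
}

#' Map a risk probability to a band
#'
#' High risk is a score in the top decile of the development score
#' distribution (`p >= t10`), medium between the decile and quintile
#' thresholds (`t20 <= p < t10`), low below the quintile threshold.
#'
#' @param probability risk probability in (0, 1)
#' @param spec an [equation_spec()] supplying the thresholds
#' @return `"low"`, `"medium"` or `"high"`
#' @export
classify_risk <- function(probability, spec) {
  stopifnot(inherits(spec, "equation_spec"))
  if (any(probability <= 0) || any(probability >= 1))
    stop("probability must lie in (0, 1)")
  thr <- spec$thresholds
  ifelse(probability >= thr["t10"], "high",
         ifelse(probability >= thr["t20"], "medium", "low"))
}

# --- unit handling --------------------------------------------------------

KG_PER_LB <- 0.45359237
CM_PER_IN <- 2.54

#' Parse a weight or length with units
#'
#' `parse_weight()` accepts a bare number (kg), `"3.2kg"` or `"7.5lb"`.
#' `parse_length()` accepts a bare number (cm), `"70cm"`, `"27.5in"` or
#' `"5ft 5in"` / `"5ft"`. Conversions: 1 lb = 0.45359237 kg, 1 in = 2.54 cm.
#'
#' @param x a number or a string with a unit suffix
#' @return the value in kg / cm
#' @export
parse_weight <- function(x) {
  if (is.numeric(x)) return(check_pos(x, "weight"))
  s <- gsub("\\s+", "", tolower(as.character(x)))
  m <- regmatches(s, regexec("^([0-9.]+)(kg|lb|lbs)?$", s))[[1]]
  if (length(m) == 0) stop("cannot parse weight '", x, "' (use kg or lb)")
  v <- as.numeric(m[2])
  if (identical(m[3], "lb") || identical(m[3], "lbs")) v <- v * KG_PER_LB
  check_pos(v, "weight")
}

#' @rdname parse_weight
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(check_pos(x, "length"))
  s <- gsub("\\s+", "", tolower(as.character(x)))
  m <- regmatches(s, regexec("^([0-9.]+)ft(([0-9.]+)in)?$", s))[[1]]
  if (length(m) > 0) {
    inches <- 12 * as.numeric(m[2]) +
      if (nzchar(m[4])) as.numeric(m[4]) else 0
    return(check_pos(inches * CM_PER_IN, "length"))
  }
  m <- regmatches(s, regexec("^([0-9.]+)(cm|in)?$", s))[[1]]
  if (length(m) == 0) stop("cannot parse length '", x, "' (use cm, in or ft/in)")
  v <- as.numeric(m[2])
  if (identical(m[3], "in")) v <- v * CM_PER_IN
  check_pos(v, "length")
}

check_pos <- function(v, what) {
  if (!is.finite(v) || v <= 0) stop(what, " must be positive, got ", v)
  v
}

#' Assess an infant's childhood-obesity risk
#'
#' The end-to-end scoring path: converts units, z-scores birth and current
#' weight against the LMS reference, computes conditional weight gain,
#' selects the equation for the assessment age (the maternal-BMI variant
#' when both maternal height and weight are given), and returns the
#' probability with its low/medium/high band.
#'
#' @param sex `"male"` or `"female"`
#' @param dob date of birth (`Date` or ISO-8601 string)
#' @param assessment_date date of the current weight measurement
#' @param birthweight birth weight; number (kg) or string with unit
#'   (see [parse_weight()])
#' @param current_weight weight at `assessment_date`; number (kg) or string
#' @param maternal_height,maternal_weight optional; both must be supplied to
#'   use the maternal-BMI equation variant (strings with units accepted)
#' @param refs an `lms_reference_set` covering birth and assessment ages
#' @param conditional_model a [conditional_model()]; defaults to
#'   [default_conditional_model()]
#' @param equations list of equations as from [published_equations()]
#' @return an object of class `risk_assessment`: equation id, probability,
#'   band, the z-scores used, and whether maternal BMI entered the score
#' @export
#' @examples
#' refs <- synthetic_lms_reference()
#' assess_infant("f", dob = "2023-01-10", assessment_date = "2023-07-20",
#'               birthweight = 3.2, current_weight = 7.9, refs = refs)
assess_infant <- function(sex, dob, assessment_date, birthweight,
                          current_weight, maternal_height = NULL,
                          maternal_weight = NULL, refs,
                          conditional_model = default_conditional_model(),
                          equations = published_equations()) {
  sex <- match_sex(sex)
  dob <- as.Date(dob); assessment_date <- as.Date(assessment_date)
  if (is.na(dob) || is.na(assessment_date)) stop("dates must be ISO-8601")
  age_days <- as.integer(assessment_date - dob)
  if (age_days <= 0) stop("assessment_date must be after dob")
  bw_kg <- parse_weight(birthweight)
  cw_kg <- parse_weight(current_weight)
  use_mbmi <- !is.null(maternal_height) && !is.null(maternal_weight)
  maternal_bmi <- if (use_mbmi) {
    h_m <- parse_length(maternal_height) / 100
    w_kg <- parse_weight(maternal_weight)
    w_kg / h_m^2
  } else NULL

  eq_id <- select_equation(age_days)
  spec <- equations[[if (use_mbmi) paste0(eq_id, "_mbmi") else eq_id]]
  bw_z <- lms_zscore(bw_kg, 0, sex, refs, "weight")
  cw_z <- lms_zscore(cw_kg, age_days, sex, refs, "weight")
  gain_z <- conditional_gain_z(bw_z, cw_z, conditional_model)
  p <- predict_probability(sex, bw_z, gain_z, spec,
                           maternal_bmi = maternal_bmi)
  structure(
    list(equation = spec$id, variant = spec$variant, probability = p,
         band = classify_risk(p, spec), age_days = age_days,
         bw_z = bw_z, current_weight_z = cw_z, gain_z = gain_z,
         maternal_bmi_used = use_mbmi,
         maternal_bmi = if (use_mbmi) maternal_bmi else NA_real_,
         thresholds = spec$thresholds),
    class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> %s (%s)\n", x$equation, x$variant))
  cat(sprintf("  probability %.4f -> %s risk\n", x$probability,
              toupper(x$band)))
  cat(sprintf("  bw_z %.3f | current weight z %.3f | conditional gain %.3f\n",
              x$bw_z, x$current_weight_z, x$gain_z))
  if (x$maternal_bmi_used)
    cat(sprintf("  maternal BMI %.1f kg/m2 included\n", x$maternal_bmi))
  invisible(x)
}
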