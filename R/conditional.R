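#' Fit a conditional weight-gain model
#'
#' Conditional weight gain expresses the follow-up weight z-score as the
#' standardized residual from its regression on the baseline z-score, so
#' that the change measure accounts for starting size and regression to the
#' mean: an infant whose follow-up weight is exactly what its birth weight
#' predicts has a conditional gain of 0 regardless of where it started.
#'
#' The model is ordinary least squares of `zt` on `z0`; `residual_sd` is the
#' root mean square residual with an n - 2 denominator.
#'
#' @param z0 baseline weight z-scores (e.g. at birth)
#' @param zt follow-up weight z-scores, same length
#' @param baseline_age_days,followup_age_days optional ages the two z-scores
#'   refer to, recorded for provenance
#' @return an object of class `conditional_model` with fields `a`
#'   (intercept), `b` (slope), `residual_sd`, `n_fit`, `degenerate` (TRUE
#'   when the fit is exact and `residual_sd` is 0)
#' @seealso [conditional_gain_z()]
#' @export
#' @examples
#' set.seed(1)
#' z0 <- rnorm(500); zt <- 0.5 * z0 + sqrt(0.75) * rnorm(500)
#' fit_conditional_model(z0, zt)
fit_conditional_model <- function(z0, zt, baseline_age_days = NA_integer_,
                                  followup_age_days = NA_integer_) {
  if (length(z0) != length(zt))
    stop("z0 and zt must have equal length")
  if (length(z0) < 3L) stop("at least 3 pairs are required")
  if (any(!is.finite(z0)) || any(!is.finite(zt)))
    stop("z0 and zt must be finite")
  sxx <- sum((z0 - mean(z0))^2)
  if (sxx == 0) stop("z0 has zero variance; conditioning slope is undefined")
  b <- sum((z0 - mean(z0)) * (zt - mean(zt))) / sxx
  a <- mean(zt) - b * mean(z0)
  res <- zt - (a + b * z0)
  rsd <- sqrt(sum(res^2) / (length(z0) - 2L))
  structure(
    list(a = a, b = b, residual_sd = rsd, n_fit = length(z0),
         degenerate = rsd == 0,
         baseline_age_days = as.integer(baseline_age_days),
         followup_age_days = as.integer(followup_age_days)),
    class = "conditional_model")
}

#' Construct a conditional model from known constants
#'
#' For scoring new infants with an externally supplied conditioning
#' regression (e.g. one estimated in a reference cohort). With standardized
#' inputs a correlation `r` corresponds to `a = 0`, `b = r`,
#' `residual_sd = sqrt(1 - r^2)`.
#'
#' @param a intercept
#' @param b slope
#' @param residual_sd positive residual standard deviation
#' @param n_fit number of pairs the constants were estimated from
#' @inheritParams fit_conditional_model
#' @return a `conditional_model`
#' @export
conditional_model <- function(a, b, residual_sd, n_fit = NA_integer_,
                              baseline_age_days = NA_integer_,
                              followup_age_days = NA_integer_) {
  stopifnot(is.finite(a), is.finite(b), is.finite(residual_sd))
  if (residual_sd <= 0) stop("residual_sd must be positive")
  structure(
    list(a = a, b = b, residual_sd = residual_sd,
         n_fit = as.integer(n_fit), degenerate = FALSE,
         baseline_age_days = as.integer(baseline_age_days),
         followup_age_days = as.integer(followup_age_days)),
    class = "conditional_model")
}

#' Default conditioning constants for scoring
#'
#' A birth-to-infancy weight z correlation of 0.5 (`a = 0`, `b = 0.5`,
#' `residual_sd = sqrt(0.75)`), a typical value for tracking of infant
#' weight; used when no cohort-estimated model is supplied.
#'
#' @return a `conditional_model`
#' @export
default_conditional_model <- function() {
  conditional_model(a = 0, b = 0.5, residual_sd = sqrt(1 - 0.5^2))
}

#' @export
print.conditional_model <- function(x, ...) {
  cat(sprintf(
    "<conditional_model> zt ~ %.4f + %.4f z0, residual sd %.4f (n = %s)%s\n",
    x$a, x$b, x$residual_sd, x$n_fit,
    if (isTRUE(x$degenerate)) " [degenerate: exact fit]" else ""))
  invisible(x)
}

#' Conditional weight z-score gain
#'
#' The standardized residual `(zt - (a + b z0)) / residual_sd`. In the
#' fitting sample these gains have mean 0, SD 1 (n - 2 denominator) and zero
#' correlation with `z0`.
#'
#' @param z0 baseline weight z-score
#' @param zt follow-up weight z-score
#' @param model a `conditional_model`
#' @return the conditional gain in SD units
#' @export
conditional_gain_z <- function(z0, zt, model) {
  stopifnot(inherits(model, "conditional_model"))
  if (isTRUE(model$degenerate))
    stop("degenerate conditional model (residual_sd = 0) cannot score gains")
  (zt - (model$a + model$b * z0)) / model$residual_sd
}

#' Composite childhood-obesity outcome rule
#'
#' The outcome flags infants whose BMI at 2 years exceeds a centile cutoff
#' (default 91st) *and* whose conditional weight z-score gain from birth to
#' 2 years exceeds one centile band. One centile band is the spacing of the
#' major UK growth-chart centile lines, two thirds of an SD (0.67 by
#' default). The gain comparator is strict `>` by default (configurable to
#' `>=`).
#'
#' @param bmi_centile_cutoff centile in (0, 100), default 91
#' @param band_width_sd width of one centile band in SD units, default 0.67
#' @param strict logical; `TRUE` uses `>` for the gain comparison
#' @return an object of class `outcome_rule`
#' @export
outcome_rule <- function(bmi_centile_cutoff = 91, band_width_sd = 0.67,
                         strict = TRUE) {
  if (bmi_centile_cutoff <= 0 || bmi_centile_cutoff >= 100)
    stop("bmi_centile_cutoff must lie in (0, 100)")
  if (band_width_sd <= 0) stop("band_width_sd must be positive")
  structure(list(bmi_centile_cutoff = bmi_centile_cutoff,
                 band_width_sd = band_width_sd, strict = isTRUE(strict)),
            class = "outcome_rule")
}

#' Evaluate the composite outcome for one or more infants
#'
#' @param bmi_z_2y BMI z-score at age 2 years
#' @param cg_0_2y conditional weight z-score gain from birth to 2 years
#' @param rule an [outcome_rule()]
#' @return logical vector: `TRUE` when both conditions hold
#' @export
#' @examples
#' outcome_flag(bmi_z_2y = 1.5, cg_0_2y = 0.8)  # TRUE
#' outcome_flag(bmi_z_2y = 1.5, cg_0_2y = 0.5)  # FALSE: gain too small
outcome_flag <- function(bmi_z_2y, cg_0_2y, rule = outcome_rule()) {
  stopifnot(inherits(rule, "outcome_rule"),
            all(is.finite(bmi_z_2y)), all(is.finite(cg_0_2y)))
  zcut <- centile_to_z(rule$bmi_centile_cutoff)
  gain_ok <- if (rule$strict) cg_0_2y > rule$band_width_sd
             else cg_0_2y >= rule$band_width_sd
  bmi_z_2y > zcut & gain_ok
}
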