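#' LMS growth reference
#'
#' An LMS reference describes an age-dependent distribution of a body
#' measurement with three curves: Box-Cox power `L`, median `M` and
#' coefficient of variation `S`. A measurement `x` at a given age maps to a
#' z-score by
#' \deqn{z = \frac{(x/M)^L - 1}{L S},}
#' with the limit \eqn{z = \log(x/M)/S} as `L` tends to 0. `L`, `M` and `S`
#' are interpolated linearly in age (days) between tabulated knots.
#'
#' `lms_reference()` builds a single-curve reference (one measurement, one
#' sex); [read_lms_reference()] reads a full set from CSV.
#'
#' @param measurement one of `"weight"`, `"length"`, `"bmi"`
#' @param sex `"male"` or `"female"`
#' @param age_days non-negative integer knot ages, strictly increasing
#' @param L,M,S numeric vectors of the same length as `age_days`; `M` and `S`
#'   must be positive
#' @return an object of class `lms_reference`
#' @seealso [lms_zscore()], [synthetic_lms_reference()]
#' @export
lms_reference <- function(measurement, sex, age_days, L, M, S) {
  measurement <- match.arg(measurement, c("weight", "length", "bmi"))
  sex <- match_sex(sex)
  n <- length(age_days)
  if (n < 2L) stop("an LMS reference needs at least two age knots")
  if (length(L) != n || length(M) != n || length(S) != n)
    stop("age_days, L, M, S must have equal length")
  if (any(age_days < 0)) stop("age_days must be non-negative")
  if (any(diff(age_days) <= 0)) {
    bad <- which(diff(age_days) <= 0)[1L] + 1L
    stop(sprintf("knot ages must be strictly increasing (row %d, age %s)",
                 bad, age_days[bad]))
  }
  if (any(!is.finite(L)) || any(!is.finite(M)) || any(!is.finite(S)))
    stop("L, M, S must be finite")
  if (any(M <= 0)) {
    stop(sprintf("M must be positive (row %d)", which(M <= 0)[1L]))
  }
  if (any(S <= 0)) {
    stop(sprintf("S must be positive (row %d)", which(S <= 0)[1L]))
  }
  structure(
    list(measurement = measurement, sex = sex,
         age_days = as.numeric(age_days),
         L = as.numeric(L), M = as.numeric(M), S = as.numeric(S)),
    class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  cat(sprintf("<lms_reference> %s, %s: %d knots, ages %g-%g days\n",
              x$measurement, x$sex, length(x$age_days),
              min(x$age_days), max(x$age_days)))
  invisible(x)
}

match_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male", "boy", "1")] <- "male"
  s[s %in% c("f", "female", "girl", "2")] <- "female"
  if (!all(s %in% c("male", "female")))
    stop(sprintf("unrecognized sex value '%s'", sex[!s %in% c("male", "female")][1L]))
  s
}

#' Read an LMS reference set from CSV
#'
#' The file must have header `measurement,sex,age_days,L,M,S` (dot decimal).
#' One `lms_reference` is built per (measurement, sex) pair, each validated
#' (strictly increasing ages, positive `M` and `S`).
#'
#' @param path path to the CSV file
#' @return an object of class `lms_reference_set`: a list of `lms_reference`
#'   objects keyed `"<measurement>.<sex>"`
#' @export
read_lms_reference <- function(path) {
  if (!file.exists(path)) stop("LMS reference file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measurement", "sex", "age_days", "L", "M", "S")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("LMS table is missing column(s): ", paste(miss, collapse = ", "))
  as_lms_reference_set(tab)
}

as_lms_reference_set <- function(tab) {
  tab$sex <- match_sex(tab$sex)
  keys <- paste(tab$measurement, tab$sex, sep = ".")
  refs <- lapply(split(tab, keys), function(d) {
    d <- d[order(d$age_days), , drop = FALSE]
    if (anyDuplicated(d$age_days)) {
      dup <- d$age_days[duplicated(d$age_days)][1L]
      stop(sprintf("duplicated age_days %s for %s/%s",
                   dup, d$measurement[1L], d$sex[1L]))
    }
    lms_reference(d$measurement[1L], d$sex[1L], d$age_days, d$L, d$M, d$S)
  })
  structure(refs, class = "lms_reference_set")
}

#' @export
print.lms_reference_set <- function(x, ...) {
  cat(sprintf("<lms_reference_set> %d references: %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write an LMS reference set to CSV
#'
#' Inverse of [read_lms_reference()].
#'
#' @param refs an `lms_reference_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_lms_reference <- function(refs, path) {
  stopifnot(inherits(refs, "lms_reference_set"))
  rows <- do.call(rbind, lapply(unname(refs), function(r) {
    data.frame(measurement = r$measurement, sex = r$sex,
               age_days = r$age_days, L = r$L, M = r$M, S = r$S)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

get_reference <- function(refs, measurement, sex) {
  stopifnot(inherits(refs, "lms_reference_set"))
  key <- paste(measurement, match_sex(sex), sep = ".")
  ref <- refs[[key]]
  if (is.null(ref))
    stop(sprintf("no %s reference for sex '%s' in this reference set",
                 measurement, sex))
  ref
}

lms_at_age <- function(ref, age_days) {
  out <- age_days < min(ref$age_days) | age_days > max(ref$age_days)
  if (any(out))
    stop(sprintf(
      "age %s days is outside the %s/%s reference span (%g-%g days)",
      age_days[out][1L], ref$measurement, ref$sex,
      min(ref$age_days), max(ref$age_days)))
  list(L = stats::approx(ref$age_days, ref$L, age_days)$y,
       M = stats::approx(ref$age_days, ref$M, age_days)$y,
       S = stats::approx(ref$age_days, ref$S, age_days)$y)
}

# below this |L| the Box-Cox transform switches to its log limit
LMS_L_EPS <- 1e-7

#' LMS z-score and its inverse
#'
#' `lms_zscore()` converts a raw measurement to an age- and sex-adjusted
#' z-score against an LMS reference; `lms_value_for_z()` inverts the
#' transform, returning the measurement value at a given z (e.g. the median
#' for z = 0). Both interpolate L, M and S linearly in age.
#'
#' @param value measurement in the reference's units (positive)
#' @param age_days age in days; must lie within the reference's knot span
#' @param sex `"male"` or `"female"` (abbreviations accepted)
#' @param refs an `lms_reference_set` (or a single `lms_reference`, in which
#'   case `sex` may be omitted)
#' @param measurement which reference to use when `refs` is a set
#' @param z z-score to invert
#' @return a dimensionless z-score (finite), or the measurement value
#' @export
#' @examples
#' refs <- synthetic_lms_reference()
#' z <- lms_zscore(8.2, age_days = 200, sex = "f", refs = refs)
#' lms_value_for_z(z, age_days = 200, sex = "f", refs = refs) # 8.2 back
lms_zscore <- function(value, age_days, sex = NULL, refs,
                       measurement = "weight") {
  ref <- if (inherits(refs, "lms_reference")) refs
         else get_reference(refs, measurement, sex)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("measurement value must be positive and finite")
  p <- lms_at_age(ref, age_days)
  n <- max(length(value), length(p$L))
  value <- rep_len(value, n); p <- lapply(p, rep_len, n)
  ifelse(abs(p$L) < LMS_L_EPS,
         log(value / p$M) / p$S,
         ((value / p$M)^p$L - 1) / (p$L * p$S))
}

#' @rdname lms_zscore
#' @export
lms_value_for_z <- function(z, age_days, sex = NULL, refs,
                            measurement = "weight") {
  ref <- if (inherits(refs, "lms_reference")) refs
         else get_reference(refs, measurement, sex)
  if (any(!is.finite(z))) stop("z must be finite")
  p <- lms_at_age(ref, age_days)
  n <- max(length(z), length(p$L))
  z <- rep_len(z, n); p <- lapply(p, rep_len, n)
  ifelse(abs(p$L) < LMS_L_EPS,
         p$M * exp(z * p$S),
         p$M * (1 + p$L * p$S * z)^(1 / p$L))
}

#' Convert between z-scores and centiles
#'
#' The standard-normal bridge used by the outcome rule ("BMI above the 91st
#' centile" corresponds to z above ~1.3408).
#'
#' @param z z-score
#' @param centile centile in the open interval (0, 100)
#' @return the corresponding centile or z-score
#' @export
#' @examples
#' z_to_centile(0)    # 50
#' centile_to_z(91)   # 1.3408
z_to_centile <- function(z) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  100 * stats::pnorm(z)
}

#' @rdname z_to_centile
#' @export
centile_to_z <- function(centile) {
  if (any(!is.finite(centile)) || any(centile <= 0) || any(centile >= 100))
    stop("centile must lie strictly between 0 and 100")
  stats::qnorm(centile / 100)
}

#' Z-score a raw measurement record
#'
#' Converts whichever of weight and length a record carries to z-scores, plus
#' a BMI z-score (BMI = kg / m^2) when both are present.
#'
#' @param weight_kg weight in kg, or `NULL`
#' @param length_cm recumbent length in cm, or `NULL`
#' @param age_days age in days
#' @param sex `"male"` or `"female"`
#' @param refs an `lms_reference_set`
#' @return a named list with elements among `weight_z`, `length_z`, `bmi_z`
#' @export
measurement_to_z <- function(weight_kg = NULL, length_cm = NULL, age_days,
                             sex, refs) {
  if (is.null(weight_kg) && is.null(length_cm))
    stop("at least one of weight_kg and length_cm is required")
  out <- list()
  if (!is.null(weight_kg))
    out$weight_z <- lms_zscore(weight_kg, age_days, sex, refs, "weight")
  if (!is.null(length_cm))
    out$length_z <- lms_zscore(length_cm, age_days, sex, refs, "length")
  if (!is.null(weight_kg) && !is.null(length_cm)) {
    bmi <- weight_kg / (length_cm / 100)^2
    out$bmi_z <- lms_zscore(bmi, age_days, sex, refs, "bmi")
  }
  out
}

#' Synthetic LMS reference for testing and examples
#'
#' A smooth parametric reference covering ages 0 to ~30 months for weight,
#' length and BMI in both sexes. The curves have the qualitative shape of UK
#' infant references (weight rising from ~3.4 kg and decelerating, length
#' from ~50 cm, BMI rising to a peak near 8 months then declining; boys
#' slightly heavier and longer) but are *synthetic*: they are generated by a
#' closed-form routine, are not fitted to any population, and must not be
#' used clinically.
#'
#' @param knot_spacing_days spacing of tabulated knots in days
#' @param max_age_days last knot age (default ~30 months)
#' @return an `lms_reference_set`
#' @export
synthetic_lms_reference <- function(knot_spacing_days = 30,
                                    max_age_days = 930) {
  age <- seq(0, max_age_days, by = knot_spacing_days)
  t <- age / 365.25
  build <- function(measurement, sex, L, M, S)
    lms_reference(measurement, sex, age, L, M, S)
  refs <- list()
  for (sex in c("male", "female")) {
    bump <- if (sex == "male") 1.035 else 1.0   # boys a few % heavier/longer
    # weight: 3.4 kg at birth, decelerating growth; mild left skew (L < 1)
    wM <- bump * (3.4 + 9.4 * t / (t + 0.62))
    wL <- 0.25 - 0.15 * t / (t + 1)
    wS <- 0.125 + 0.02 * exp(-t / 0.5)
    refs[[paste0("weight.", sex)]] <- build("weight", sex, wL, wM, wS)
    # length: near-symmetric (L ~ 1), small CV
    lM <- (if (sex == "male") 1.01 else 1.0) * (50 + 38 * t / (t + 0.95))
    lL <- rep(1, length(age))
    lS <- 0.035 + 0.004 * exp(-t / 0.4)
    refs[[paste0("length.", sex)]] <- build("length", sex, lL, lM, lS)
    # BMI: rises to ~17.5 around 8 months, declines toward 16; right skew
    bM <- (if (sex == "male") 1.01 else 1.0) *
      (13.3 + 4.3 * exp(-((t - 0.66) / 1.15)^2))
    bL <- -0.6 + 0.2 * t / (t + 1)
    bS <- 0.08 + 0.01 * exp(-t / 0.6)
    refs[[paste0("bmi.", sex)]] <- build("bmi", sex, bL, bM, bS)
  }
  structure(refs, class = "lms_reference_set")
}
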