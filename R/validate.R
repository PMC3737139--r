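#' Area under the ROC curve with DeLong confidence interval
#'
#' The Mann-Whitney estimator: the probability that a randomly chosen case
#' scores higher than a randomly chosen control, with ties counting one
#' half. Computed via mid-ranks, so it equals exhaustive pair counting
#' exactly. The confidence interval uses the DeLong placement-value
#' variance with a normal approximation, truncated to [0, 1].
#'
#' @param scores numeric risk scores
#' @param labels 0/1 or logical outcome; both classes must be present
#' @param conf_level confidence level (default 0.95)
#' @return a list of class `auc_result`: `auc`, `se`, `ci`, `n_cases`,
#'   `n_controls`
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))$auc  # 0.75
auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                       # mid-ranks handle ties as 1/2
  a <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
  # DeLong placement values via ranks: for case i, the fraction of controls
  # below it (ties 1/2) is (overall rank - within-case rank)/n0
  rx <- rank(scores[labels == 1])
  ry <- rank(scores[labels == 0])
  v10 <- (r[labels == 1] - rx) / n0
  v01 <- 1 - (r[labels == 0] - ry) / n1
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  se <- sqrt(s10 / n1 + s01 / n0)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(a + c(-1, 1) * zq * se, 0), 1)
  structure(list(auc = a, se = se, ci = ci, n_cases = n1, n_controls = n0),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d cases, %d controls)\n",
              x$auc, x$ci[1], x$ci[2], x$n_cases, x$n_controls))
  invisible(x)
}

clopper_pearson <- function(x, n, conf_level = 0.95) {
  a <- 1 - conf_level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Threshold diagnostics at score-distribution cut-offs
#'
#' For each population proportion `q` (default 30%, 20%, 10%), the score
#' threshold is the empirical order statistic at `ceiling((1 - q) n)`;
#' test-positive means `score >= threshold` (ties are admitted above the
#' threshold). Sensitivity, specificity, PPV and NPV come from the
#' resulting 2x2 table, with exact Clopper-Pearson 95% intervals.
#'
#' @param scores numeric risk scores
#' @param labels 0/1 outcome; both classes required
#' @param proportions cut-off proportions in (0, 1)
#' @param conf_level confidence level for the rate CIs
#' @return a data frame with one row per proportion: `proportion`,
#'   `threshold`, `n_positive`, then `sensitivity`, `specificity`, `ppv`,
#'   `npv` in percent, each with `_lo`/`_hi` CI columns
#' @export
diagnostics_at_cutoffs <- function(scores, labels,
                                   proportions = c(0.3, 0.2, 0.1),
                                   conf_level = 0.95) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (sum(labels) == 0 || sum(labels) == length(labels))
    stop("both classes must be present")
  if (any(proportions <= 0) || any(proportions >= 1))
    stop("proportions must lie in (0, 1)")
  n <- length(scores)
  srt <- sort(scores)
  rows <- lapply(proportions, function(q) {
    thr <- srt[ceiling((1 - q) * n)]
    pos <- scores >= thr
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    fn <- sum(!pos & labels == 1); tn <- sum(!pos & labels == 0)
    rate <- function(x, nn) {
      ci <- clopper_pearson(x, nn, conf_level)
      c(100 * x / nn, 100 * ci)
    }
    sens <- rate(tp, tp + fn); spec <- rate(tn, tn + fp)
    ppv <- rate(tp, tp + fp);  npv <- rate(tn, tn + fn)
    data.frame(proportion = q, threshold = thr, n_positive = tp + fp,
               sensitivity = sens[1], sensitivity_lo = sens[2],
               sensitivity_hi = sens[3],
               specificity = spec[1], specificity_lo = spec[2],
               specificity_hi = spec[3],
               ppv = ppv[1], ppv_lo = ppv[2], ppv_hi = ppv[3],
               npv = npv[1], npv_lo = npv[2], npv_hi = npv[3])
  })
  do.call(rbind, rows)
}

#' Reconstruct a 2x2 diagnostic table from summary figures
#'
#' Integer back-solving of a published diagnostics row: given the sample
#' size, case count, sensitivity and PPV (in percent), recovers the
#' confusion-table counts and the remaining rates. Useful for consistency
#' checks against printed diagnostics tables.
#'
#' @param n total sample size
#' @param n_cases number of outcome-positive subjects
#' @param sensitivity,ppv percentages
#' @return a list with `tp`, `fp`, `fn`, `tn`, `n_positive` and
#'   `sensitivity`, `specificity`, `ppv`, `npv` in percent
#' @export
reconstruct_diagnostics <- function(n, n_cases, sensitivity, ppv) {
  tp <- round(sensitivity / 100 * n_cases)
  n_pos <- round(tp / (ppv / 100))
  fp <- n_pos - tp
  fn <- n_cases - tp
  tn <- n - n_cases - fp
  list(tp = tp, fp = fp, fn = fn, tn = tn, n_positive = n_pos,
       sensitivity = 100 * tp / n_cases,
       specificity = 100 * tn / (n - n_cases),
       ppv = 100 * tp / n_pos,
       npv = 100 * tn / (tn + fn))
}

#' Bootstrap internal validation
#'
#' Draws `B` resamples of the cohort with replacement at the original size,
#' re-runs the full fitting-and-selection procedure on each, and summarizes
#' the coefficient distributions and term retention frequencies. The "final
#' bootstrap model" contains the terms whose bootstrap 95% percentile
#' interval excludes 0 (unretained reps contribute a 0 coefficient);
#' `rule = "retention"` instead keeps terms retained in at least half the
#' reps. That model is refitted on the original sample and its AUC on the
#' original sample is reported. Resamples where fitting fails (e.g. through
#' separation) are skipped and counted.
#'
#' @inheritParams backward_stepwise
#' @param B number of bootstrap repetitions
#' @param seed optional integer seed for reproducible resampling
#' @param rule `"percentile"` (default) or `"retention"` term-summary rule
#' @return a list of class `bootstrap_result`: `B`, `coefficients` (B x term
#'   matrix, 0 when a term was not retained), `retention` (per-term
#'   frequencies), `final_terms`, `final_fit` (a `development_result` on the
#'   original sample), `auc_on_original`, `n_skipped`
#' @export
bootstrap_validate <- function(cohort, candidates,
                               interactions = character(), B = 1000L,
                               seed = NULL, alpha = 0.05,
                               forced = character(),
                               rule = c("percentile", "retention"),
                               outcome = "outcome") {
  rule <- match.arg(rule)
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  all_terms <- c(candidates, interactions)
  coef_by_term <- function(res) {
    # one representative coefficient per term (first design column; for the
    # education block that is the first dummy)
    out <- stats::setNames(numeric(length(all_terms)), all_terms)
    for (tm in res$terms)
      out[tm] <- res$coefficients[res$term_columns[[tm]][1L]]
    out
  }
  mat <- matrix(NA_real_, nrow = B, ncol = length(all_terms),
                dimnames = list(NULL, all_terms))
  retained <- matrix(FALSE, nrow = B, ncol = length(all_terms),
                     dimnames = list(NULL, all_terms))
  n_skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      backward_stepwise(cohort[idx, , drop = FALSE], candidates,
                        interactions, alpha = alpha, forced = forced,
                        outcome = outcome),
      error = function(e) NULL)
    if (is.null(res)) { n_skipped <- n_skipped + 1L; next }
    mat[b, ] <- 0
    mat[b, res$terms] <- coef_by_term(res)[res$terms]
    retained[b, res$terms] <- TRUE
  }
  ok <- stats::complete.cases(mat)
  retention <- colMeans(retained[ok, , drop = FALSE])
  final_terms <- if (rule == "percentile") {
    keep <- apply(mat[ok, , drop = FALSE], 2, function(v) {
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      q[1] > 0 || q[2] < 0
    })
    all_terms[keep]
  } else all_terms[retention >= 0.5]
  final_terms <- union(forced, final_terms)
  # drop interactions whose mains did not make it
  final_terms <- final_terms[vapply(final_terms, function(tm) {
    mains <- strsplit(tm, ":")[[1]]
    all(mains %in% final_terms) || !grepl(":", tm)
  }, logical(1))]
  final_fit <- backward_stepwise(cohort, intersect(candidates, final_terms),
                                 intersect(interactions, final_terms),
                                 alpha = 1, forced = final_terms,
                                 outcome = outcome)
  structure(list(B = B, coefficients = mat[ok, , drop = FALSE],
                 retention = retention, final_terms = final_terms,
                 final_fit = final_fit, auc_on_original = final_fit$auc,
                 n_skipped = n_skipped),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d (%d skipped)\n", x$B, x$n_skipped))
  cat("retention frequencies:\n"); print(round(x$retention, 3))
  cat("final bootstrap model terms: ",
      paste(x$final_terms, collapse = ", "), "\n")
  if (!is.null(x$auc_on_original))
    cat(sprintf("AUC on original sample: %.3f (%.3f-%.3f)\n",
                x$auc_on_original$auc, x$auc_on_original$ci[1],
                x$auc_on_original$ci[2]))
  invisible(x)
}

#' Apply a frozen risk equation to an external cohort
#'
#' Scores every record with [predict_probability()] using the equation's
#' fixed published coefficients (no refitting) and reports discrimination
#' against the cohort's observed outcome.
#'
#' @param spec an [equation_spec()]
#' @param cohort a cohort data frame with `sex`, `bw_z`, `gain_z`,
#'   `outcome` (plus `maternal_bmi` for the `with_maternal_bmi` variant)
#' @param conf_level confidence level for the AUC CI
#' @return a list: `auc` (an `auc_result`), `scores`, `n`
#' @export
external_validate <- function(spec, cohort, conf_level = 0.95) {
  stopifnot(inherits(spec, "equation_spec"), is.data.frame(cohort))
  need <- c("sex", "bw_z", "gain_z", "outcome")
  if (spec$variant == "with_maternal_bmi") need <- c(need, "maternal_bmi")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing required field(s): ",
                         paste(miss, collapse = ", "))
  scores <- predict_probability(
    cohort$sex, cohort$bw_z, cohort$gain_z, spec,
    maternal_bmi = if (spec$variant == "with_maternal_bmi")
      cohort$maternal_bmi else NULL)
  list(auc = auc(scores, cohort$outcome, conf_level), scores = scores,
       n = nrow(cohort))
}
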