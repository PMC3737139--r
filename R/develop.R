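# cohort field schema shared by development, simulation and IO
COHORT_COLUMNS <- c("subject_id", "sex", "ethnicity", "bw_z", "gain_z",
                    "bmi_z_2y", "maternal_bmi", "education", "smoked",
                    "gdm", "preterm", "outcome")
ETHNICITY_LEVELS <- c("white_british", "south_asian")
EDUCATION_LEVELS <- c("lt5_gcse", "gcse5plus", "alevel", "degree", "other")
ALLOWED_INTERACTIONS <- c("sex:bw_z", "sex:gain_z",
                          "ethnicity:bw_z", "ethnicity:gain_z")

#' Maximum-likelihood logistic regression by Newton/IRLS
#'
#' Fits `logit P(y = 1) = X b` by iteratively reweighted least squares,
#' stopping when the maximum absolute score (gradient of the log-likelihood)
#' falls below `1e-8`. Complete separation is detected explicitly (the
#' fitted direction perfectly splits cases from controls while coefficients
#' diverge) and raised as an error rather than returned as a silently
#' divergent fit.
#'
#' @param y 0/1 (or logical) outcome vector
#' @param X design matrix including an intercept column; `n > ncol(X)`
#'   required, no constant column besides the intercept
#' @param max_iter maximum Newton iterations (default 100)
#' @param tol gradient-norm convergence tolerance
#' @return a list of class `logistic_fit`: `coefficients`, `vcov` (inverse
#'   observed information), `se`, `loglik`, `deviance`, `iterations`,
#'   `fitted`, `gradient_norm`
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- rbinom(200, 1, plogis(-1 + x))
#' fit_logistic(y, cbind(1, x))$coefficients
fit_logistic <- function(y, X, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (n <= ncol(X)) stop("more parameters than observations")
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  intercept_like <- apply(X, 2, function(c) all(c == c[1L]))
  if (sum(intercept_like) > 1L)
    stop("design has a constant column besides the intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient; drop collinear columns")

  beta <- numeric(ncol(X))
  for (iter in seq_len(max_iter)) {
    lp <- drop(X %*% beta)
    p <- stats::plogis(lp)
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < tol) break
    # complete separation: the current direction splits the classes and the
    # likelihood pushes the coefficients off to infinity
    if (max(abs(beta)) > 15 &&
        max(lp[y == 0]) < min(lp[y == 1]))
      stop("complete separation detected: maximum likelihood does not exist")
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("information matrix is singular (near-separation or collinearity)"))
    # dampen absurd steps to keep Newton stable far from the optimum
    if (max(abs(step)) > 20) step <- step * 20 / max(abs(step))
    beta <- beta + step
    if (iter == max_iter)
      stop("IRLS did not converge in ", max_iter, " iterations")
  }
  lp <- drop(X %*% beta)
  p <- stats::plogis(lp)
  grad <- drop(crossprod(X, y - p))
  if (max(abs(grad)) >= tol)
    stop("IRLS did not converge: gradient norm ", format(max(abs(grad))))
  w <- p * (1 - p)
  V <- solve(crossprod(X * w, X))
  ll <- sum(y * lp - log1p(exp(lp)))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, vcov = V,
                 se = stats::setNames(sqrt(diag(V)), colnames(X)),
                 loglik = ll, deviance = -2 * ll, iterations = iter,
                 fitted = p, gradient_norm = max(abs(grad))),
            class = "logistic_fit")
}

# --- term machinery for stepwise selection --------------------------------

# build a model frame with properly typed columns from a cohort table
cohort_model_frame <- function(cohort) {
  mf <- cohort
  if ("sex" %in% names(mf))
    mf$sex <- factor(match_sex(mf$sex), levels = c("male", "female"))
  if ("ethnicity" %in% names(mf))
    mf$ethnicity <- factor(mf$ethnicity, levels = ETHNICITY_LEVELS)
  if ("education" %in% names(mf))
    mf$education <- factor(mf$education, levels = EDUCATION_LEVELS)
  for (col in c("smoked", "gdm", "preterm"))
    if (col %in% names(mf)) mf[[col]] <- as.numeric(mf[[col]])
  mf
}

build_design <- function(cohort, terms) {
  mf <- cohort_model_frame(cohort)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(f, data = mf)
  assign <- attr(X, "assign")          # 0 = intercept, k = k-th term
  term_labels <- attr(stats::terms(f), "term.labels")
  # terms() reorders interaction components (a:b may become b:a); map the
  # canonical labels back to the caller's term names
  key <- function(t) paste(sort(strsplit(t, ":")[[1]]), collapse = ":")
  term_labels <- vapply(term_labels, function(lb)
    terms[match(key(lb), vapply(terms, key, character(1)))], character(1),
    USE.NAMES = FALSE)
  list(X = X, assign = assign, term_labels = term_labels)
}

# joint Wald test of all design columns belonging to one term
term_wald_p <- function(fit, cols) {
  b <- fit$coefficients[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  W <- drop(t(b) %*% solve(V) %*% b)
  stats::pchisq(W, df = length(cols), lower.tail = FALSE)
}

#' Backward stepwise logistic model development
#'
#' Re-derives a risk equation from a cohort table: all candidate predictors
#' (and optionally the four screened interactions: sex or ethnicity crossed
#' with birthweight z or gain z) enter a logistic model, then the term with
#' the largest Wald p-value at or above `alpha` is removed and the model
#' refitted, until every remaining term is significant. Interactions are
#' eligible for removal before their main effects; a main effect can only
#' leave once no retained interaction contains it. Multi-level factors
#' (education) are removed or retained as a block via a joint Wald test.
#' Ties in p-values are broken by removing the term declared later, so the
#' procedure is deterministic given the candidate order. Rank-deficient
#' designs (e.g. duplicated covariates) are repaired before fitting by
#' dropping the later-declared offending term.
#'
#' @param cohort a cohort data frame (see [read_cohort()] for the schema);
#'   extra numeric columns may be used as candidates
#' @param candidates character vector of predictor column names
#' @param interactions character vector among
#'   `"sex:bw_z"`, `"sex:gain_z"`, `"ethnicity:bw_z"`, `"ethnicity:gain_z"`
#' @param alpha retention p-value threshold (default 0.05)
#' @param forced terms always retained regardless of p (e.g. `"sex"` when
#'   developing a sex-adjusted scoring equation)
#' @param outcome name of the 0/1 outcome column
#' @return an object of class `development_result`: retained `terms`,
#'   `coefficients`, `se`, `p_values` (per term), `vcov`, `or_table`
#'   (via [development_ors()]), `auc` (with CI, on the development sample),
#'   `n`, `removed` (removal order), `dropped_rank_deficient`, `iterations`
#' @export
backward_stepwise <- function(cohort, candidates,
                              interactions = character(),
                              alpha = 0.05, forced = character(),
                              outcome = "outcome") {
  stopifnot(is.data.frame(cohort), outcome %in% names(cohort))
  bad <- setdiff(candidates, names(cohort))
  if (length(bad)) stop("unknown candidate column(s): ",
                        paste(bad, collapse = ", "))
  bad_int <- setdiff(interactions, ALLOWED_INTERACTIONS)
  if (length(bad_int))
    stop("interactions must be among ",
         paste(ALLOWED_INTERACTIONS, collapse = ", "))
  for (int in interactions) {
    mains <- strsplit(int, ":")[[1]]
    if (!all(mains %in% candidates))
      stop("interaction ", int, " requires its main effects among candidates")
  }
  y <- as.numeric(cohort[[outcome]])
  terms <- c(candidates, interactions)     # declared order; later = removed on ties
  removed <- character()
  dropped_rd <- character()

  repeat {
    # repair rank deficiency by dropping later-declared terms
    repeat {
      d <- build_design(cohort, terms)
      if (qr(d$X)$rank == ncol(d$X) || length(terms) == 0L) break
      # find terms whose columns are linearly dependent, drop the latest one
      piv <- qr(d$X, LAPACK = FALSE)
      dep_cols <- piv$pivot[-seq_len(piv$rank)]
      dep_terms <- unique(d$term_labels[d$assign[dep_cols]])
      victim <- dep_terms[length(dep_terms)]
      terms <- setdiff(terms, victim)
      dropped_rd <- c(dropped_rd, victim)
    }
    fit <- fit_logistic(y, d$X)
    if (length(terms) == 0L) break
    # p-value per term (joint Wald for multi-column terms)
    pvals <- vapply(seq_along(d$term_labels), function(k)
      term_wald_p(fit, which(d$assign == k)), numeric(1))
    names(pvals) <- d$term_labels
    # removal eligibility: forced never; mains with a retained interaction never
    in_interaction <- unique(unlist(strsplit(
      grep(":", terms, value = TRUE), ":")))
    eligible <- setdiff(terms, forced)
    eligible <- eligible[!(eligible %in% in_interaction) | grepl(":", eligible)]
    if (length(eligible) == 0L) break
    pe <- pvals[eligible]
    if (all(pe < alpha)) break
    worst <- max(pe)
    # ties: remove the later term in declared order
    cand <- names(pe)[pe == worst]
    victim <- cand[which.max(match(cand, terms))]
    terms <- setdiff(terms, victim)
    removed <- c(removed, victim)
  }

  d <- build_design(cohort, terms)
  final_p <- if (length(terms))
    stats::setNames(vapply(seq_along(d$term_labels), function(k)
      term_wald_p(fit, which(d$assign == k)), numeric(1)), d$term_labels)
  else stats::setNames(numeric(0), character(0))
  auc_res <- if (length(unique(y)) == 2L) auc(fit$fitted, y) else NULL
  term_columns <- stats::setNames(lapply(seq_along(d$term_labels), function(k)
    colnames(d$X)[d$assign == k]), d$term_labels)
  res <- structure(
    list(terms = terms, coefficients = fit$coefficients, se = fit$se,
         term_columns = term_columns,
         p_values = final_p, vcov = fit$vcov, loglik = fit$loglik,
         deviance = fit$deviance, auc = auc_res, n = length(y),
         removed = removed, dropped_rank_deficient = dropped_rd,
         iterations = fit$iterations, fit = fit),
    class = "development_result")
  res$or_table <- development_ors(res)
  res
}

#' @export
print.development_result <- function(x, ...) {
  cat(sprintf("<development_result> n = %d, retained: %s\n", x$n,
              if (length(x$terms)) paste(x$terms, collapse = ", ")
              else "(intercept only)"))
  print(round(x$or_table, 3))
  if (!is.null(x$auc))
    cat(sprintf("AUC %.1f%% (%.1f-%.1f%%)\n", 100 * x$auc$auc,
                100 * x$auc$ci[1], 100 * x$auc$ci[2]))
  invisible(x)
}

#' Odds-ratio table for a fitted development model
#'
#' `OR = exp(b)` with 95% CI `exp(b +/- 1.959964 SE)` for every
#' non-intercept coefficient.
#'
#' @param result a `development_result` (or any `logistic_fit`)
#' @return a matrix with columns `coef`, `se`, `or`, `ci_lo`, `ci_hi`, `p`
#' @export
development_ors <- function(result) {
  b <- result$coefficients
  se <- result$se
  keep <- names(b) != "(Intercept)"
  b <- b[keep]; se <- se[keep]
  zq <- 1.959964
  p <- stats::pchisq((b / se)^2, df = 1, lower.tail = FALSE)
  cbind(coef = b, se = se, or = exp(b),
        ci_lo = exp(b - zq * se), ci_hi = exp(b + zq * se), p = p)
}
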