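#' Read and write cohort tables
#'
#' The cohort CSV has header
#' `subject_id,sex,ethnicity,bw_z,gain_z,bmi_z_2y,maternal_bmi,education,smoked,gdm,preterm,outcome`
#' with booleans coded 0/1, sex as `male`/`female`, ethnicity as
#' `white_british`/`south_asian` and education as one of `lt5_gcse`,
#' `gcse5plus`, `alevel`, `degree`, `other`. Validation failures report the
#' offending row. An empty file with a header yields an empty cohort, not
#' an error.
#'
#' @param path CSV path
#' @param cohort a cohort data frame
#' @return `read_cohort()`: a validated cohort data frame;
#'   `write_cohort()`: `path`, invisibly
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  unknown <- setdiff(names(tab), COHORT_COLUMNS)
  if (length(unknown))
    stop("unknown column(s) in cohort file: ", paste(unknown, collapse = ", "))
  miss <- setdiff(COHORT_COLUMNS, names(tab))
  if (length(miss))
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "))
  validate_cohort(tab)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[COHORT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the schema of [read_cohort()]: enum fields, 0/1 booleans and
#' finite z-scores, reporting the first offending row. Complete cases are
#' required (equation development is complete-case).
#'
#' @param cohort a data frame
#' @return the cohort, invisibly typed (booleans as integer)
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) return(cohort)
  fail <- function(col, i, val)
    stop(sprintf("cohort row %d: invalid %s '%s'", i, col, val))
  chk_enum <- function(col, levels) {
    bad <- which(!cohort[[col]] %in% levels)
    if (length(bad)) fail(col, bad[1L], cohort[[col]][bad[1L]])
  }
  chk_enum("sex", c("male", "female"))
  chk_enum("ethnicity", ETHNICITY_LEVELS)
  chk_enum("education", EDUCATION_LEVELS)
  for (col in c("smoked", "gdm", "preterm", "outcome")) {
    bad <- which(!cohort[[col]] %in% c(0, 1))
    if (length(bad)) fail(col, bad[1L], cohort[[col]][bad[1L]])
    cohort[[col]] <- as.integer(cohort[[col]])
  }
  for (col in c("bw_z", "gain_z", "bmi_z_2y", "maternal_bmi")) {
    v <- cohort[[col]]
    if (!is.numeric(v)) fail(col, which(is.na(suppressWarnings(
      as.numeric(v))))[1L], "non-numeric")
    bad <- which(!is.finite(v))
    if (length(bad)) fail(col, bad[1L], v[bad[1L]])
  }
  cohort
}

# --- model configuration --------------------------------------------------

MODEL_CONFIG_SCHEMA <- "growthrisk-model-config/1"

#' Save and load a model configuration
#'
#' A model configuration bundles the scoring constants the tool needs:
#' the equation specs (published or freshly developed), the conditioning
#' regression constants, the outcome rule and optionally a reference file
#' path. Serialized as JSON (YAML also readable when the `yaml` package is
#' available) with an explicit `schema_version`, so updated equations can
#' ship as configuration rather than code. Numeric values are written at
#' full precision: a saved-and-reloaded configuration reproduces
#' bit-identical probabilities.
#'
#' @param equations named list of [equation_spec()]s
#' @param conditional_model a [conditional_model()]
#' @param outcome_rule an [outcome_rule()]
#' @param reference_path optional path to an LMS reference CSV
#' @param path file path (`.json`, `.yaml` or `.yml`)
#' @return `load_model_config()`: a list of class `model_config` with
#'   elements `schema_version`, `equations`, `conditional_model`,
#'   `outcome_rule`, `reference_path`
#' @export
save_model_config <- function(path, equations = published_equations(),
                              conditional_model = default_conditional_model(),
                              outcome_rule = NULL,
                              reference_path = NULL) {
  if (is.null(outcome_rule)) outcome_rule <- growthrisk::outcome_rule()
  stopifnot(all(vapply(equations, inherits, logical(1), "equation_spec")))
  obj <- list(
    schema_version = MODEL_CONFIG_SCHEMA,
    equations = lapply(equations, function(e) {
      u <- unclass(e)
      u$thresholds <- as.list(u$thresholds)
      u
    }),
    conditional_model = unclass(conditional_model),
    outcome_rule = unclass(outcome_rule),
    reference_path = reference_path)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_model_config
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("schema_version", "equations", "conditional_model",
              "outcome_rule"))
    if (is.null(obj[[f]]))
      stop("model config schema violation: missing field '", f, "'")
  if (!identical(obj$schema_version, MODEL_CONFIG_SCHEMA))
    stop("unrecognized model config schema_version: ", obj$schema_version)
  eqs <- lapply(obj$equations, function(e) {
    for (f in c("id", "variant", "alpha", "beta_female", "beta_bw_z",
                "beta_gain_z", "thresholds"))
      if (is.null(e[[f]]))
        stop("model config schema violation: equations[].", f)
    thr <- e$thresholds
    if (any(!c("t10", "t20", "t30") %in% names(thr)))
      stop("model config schema violation: equations[].thresholds")
    equation_spec(e$id, e$variant, alpha = e$alpha,
                  beta_female = e$beta_female, beta_bw_z = e$beta_bw_z,
                  beta_gain_z = e$beta_gain_z,
                  beta_maternal_bmi = e$beta_maternal_bmi,
                  t10 = thr$t10, t20 = thr$t20, t30 = thr$t30)
  })
  cm <- obj$conditional_model
  rule <- obj$outcome_rule
  structure(
    list(schema_version = obj$schema_version, equations = eqs,
         conditional_model = conditional_model(
           a = cm$a, b = cm$b, residual_sd = cm$residual_sd,
           n_fit = if (is.null(cm$n_fit)) NA_integer_ else cm$n_fit),
         outcome_rule = outcome_rule(rule$bmi_centile_cutoff,
                                     rule$band_width_sd, rule$strict),
         reference_path = obj$reference_path),
    class = "model_config")
}
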