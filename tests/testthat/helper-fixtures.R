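# shared fixtures, built in code at test time

test_refs <- synthetic_lms_reference()

# a single-curve reference with hand-picked constants for closed-form checks
flat_ref <- function(L, M, S, measurement = "weight", sex = "male") {
  lms_reference(measurement, sex, age_days = c(0, 1000),
                L = c(L, L), M = c(M, M), S = c(S, S))
}

# small model-mode cohort reused across IO / validation tests
small_cohort <- function(n = 500, seed = 42, ...) {
  simulate_model_mode(simulation_config(n = n, seed = seed, ...))
}

# exhaustive pair-counting AUC oracle (independent of the rank-based path)
auc_pairs <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > controls) + 0.5 * sum(x == controls)
  tot / (length(cases) * length(controls))
}

# write a small LMS CSV and return its path
write_test_ref_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "ref.csv")
  write_lms_reference(test_refs, path)
  path
}
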