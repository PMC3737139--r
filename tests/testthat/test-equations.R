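eqs <- published_equations()

test_that("the six embedded equations carry the published constants", {
  expect_length(eqs, 6L)
  expect_equal(eqs$eq3$beta_gain_z, 2.174)
  expect_equal(eqs$eq1$alpha, -3.718)
  expect_equal(eqs$eq1$beta_female, 0.488)
  expect_equal(eqs$eq1$beta_bw_z, 0.599)
  expect_equal(eqs$eq2_mbmi$beta_maternal_bmi, 0.046)
  expect_equal(unname(eqs$eq1$thresholds["t10"]), 0.2072)
  expect_equal(unname(eqs$eq3$thresholds), c(0.2391, 0.1065, 0.0609))
  for (e in eqs) {
    expect_true(e$thresholds["t10"] > e$thresholds["t20"])
    expect_true(e$thresholds["t20"] > e$thresholds["t30"])
    expect_equal(diff(e$window_months), 3)
    if (e$variant == "with_maternal_bmi")
      expect_false(is.null(e$beta_maternal_bmi))
  }
})

test_that("equation windows are half-open and bounded at 4.5-13.5 months", {
  expect_equal(select_equation(183), "eq1")              # ~6.0 months
  expect_equal(select_equation(4.5 * 30.4375), "eq1")    # lower bound in
  expect_equal(select_equation(7.5 * 30.4375), "eq2")    # boundary -> eq2
  expect_equal(select_equation(10.5 * 30.4375), "eq3")
  expect_equal(select_equation(13.5 * 30.4375), "eq3")   # upper bound in
  expect_error(select_equation(14 * 30.4375), "outside")
  expect_error(select_equation(120), "outside")
})

test_that("predicted probability is the logistic of the linear predictor", {
  expect_equal(predict_probability("male", 0, 0, eqs$eq1),
               stats::plogis(-3.718))
  expect_equal(round(predict_probability("male", 0, 0, eqs$eq1), 5), 0.02371)
  expect_equal(predict_probability("female", 1, 1, eqs$eq3),
               stats::plogis(-3.937 + 0.234 + 0.824 + 2.174))
  expect_equal(round(predict_probability("female", 1, 1, eqs$eq3), 4), 0.3307)
  # maternal-BMI variant requires maternal BMI
  expect_error(predict_probability("f", 0, 0, eqs$eq1_mbmi),
               "requires maternal_bmi")
  p <- predict_probability("f", 0, 0, eqs$eq1_mbmi, maternal_bmi = 26)
  expect_equal(p, stats::plogis(-4.920 + 0.493 + 0.044 * 26))
  expect_error(predict_probability("f", NA, 0, eqs$eq1), "finite")
  # range and monotonicity
  g <- seq(-4, 4, by = 0.5)
  p <- predict_probability("male", 0, g, eqs$eq2)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(predict_probability("male", g, 0, eqs$eq2)) > 0))
})

test_that("banding follows the decile/quintile thresholds", {
  expect_equal(unname(classify_risk(0.25, eqs$eq1)), "high")
  expect_equal(unname(classify_risk(0.15, eqs$eq1)), "medium")
  expect_equal(unname(classify_risk(0.05, eqs$eq1)), "low")
  expect_equal(unname(classify_risk(eqs$eq1$thresholds["t10"], eqs$eq1)),
               "high")                                      # boundary is high
  expect_error(classify_risk(0, eqs$eq1), "0, 1")
  # increasing gain never lowers the band
  bands <- c(low = 1L, medium = 2L, high = 3L)
  p <- predict_probability("female", 0.2, seq(-2, 3, by = 0.1), eqs$eq3)
  b <- bands[classify_risk(p, eqs$eq3)]
  expect_true(all(diff(b) >= 0))
})

test_that("exp of the eq3 birthweight coefficient matches the published OR", {
  expect_equal(round(exp(eqs$eq3$beta_bw_z), 2), 2.28)
})

test_that("unit parsing converts pounds and feet/inches exactly", {
  expect_equal(parse_weight("1lb"), 0.45359237)
  expect_equal(parse_weight("3.2kg"), 3.2)
  expect_equal(parse_weight(3.2), 3.2)
  expect_equal(parse_length("1in"), 2.54)
  expect_equal(parse_length("5ft 6in"), 66 * 2.54)
  expect_equal(parse_length("5ft"), 60 * 2.54)
  expect_equal(parse_length("165cm"), 165)
  expect_error(parse_weight("3.2stone"), "cannot parse")
  expect_error(parse_weight("-2kg"), "cannot parse")
  expect_error(parse_weight(-2), "positive")
})

test_that("assessment is invariant to input units", {
  a_metric <- assess_infant("f", "2023-01-10", "2023-07-20",
                            birthweight = 3.2, current_weight = 7.9,
                            maternal_height = 165, maternal_weight = 70,
                            refs = test_refs)
  a_imperial <- assess_infant("f", "2023-01-10", "2023-07-20",
                              birthweight = sprintf("%.10flb", 3.2 / 0.45359237),
                              current_weight = sprintf("%.10flb", 7.9 / 0.45359237),
                              maternal_height = sprintf("%.10fin", 165 / 2.54),
                              maternal_weight = sprintf("%.10flb", 70 / 0.45359237),
                              refs = test_refs)
  expect_equal(a_metric$probability, a_imperial$probability, tolerance = 1e-9)
  expect_equal(a_metric$band, a_imperial$band)
})

test_that("maternal fields switch the variant; medians give the intercept", {
  base <- assess_infant("m", "2023-01-01", "2023-07-01", 3.5, 8.0,
                        refs = test_refs)
  expect_equal(base$variant, "base")
  expect_false(base$maternal_bmi_used)
  both <- assess_infant("m", "2023-01-01", "2023-07-01", 3.5, 8.0,
                        maternal_height = 165, maternal_weight = 70,
                        refs = test_refs)
  expect_equal(both$variant, "with_maternal_bmi")
  # an infant at the reference medians at both ages scores the intercept
  # (+ sex term) exactly: bw_z = 0 and gain_z = 0
  age <- 183L
  w0 <- lms_value_for_z(0, 0, "female", test_refs, "weight")
  wa <- lms_value_for_z(0, age, "female", test_refs, "weight")
  med <- assess_infant("female", "2023-01-01",
                       as.Date("2023-01-01") + age, w0, wa,
                       refs = test_refs)
  expect_equal(med$bw_z, 0, tolerance = 1e-9)
  expect_equal(med$gain_z, 0, tolerance = 1e-9)
  expect_equal(med$probability, stats::plogis(-3.718 + 0.488),
               tolerance = 1e-9)
  expect_error(assess_infant("m", "2023-07-01", "2023-01-01", 3.5, 8,
                             refs = test_refs), "after dob")
})

test_that("serialized equations reload to bit-identical probabilities", {
  path <- file.path(tempdir(), "eqs.json")
  save_model_config(path, equations = eqs)
  back <- load_model_config(path)$equations
  grid <- expand.grid(sex = c("male", "female"), bw = seq(-2, 2, 0.5),
                      gain = seq(-2, 2, 0.5), stringsAsFactors = FALSE)
  for (key in names(eqs)) {
    mb <- if (eqs[[key]]$variant == "with_maternal_bmi") 27.3 else NULL
    p1 <- predict_probability(grid$sex, grid$bw, grid$gain, eqs[[key]],
                              maternal_bmi = mb)
    p2 <- predict_probability(grid$sex, grid$bw, grid$gain, back[[key]],
                              maternal_bmi = mb)
    expect_identical(p1, p2)
  }
})
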