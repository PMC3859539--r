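# The tax-to-consumption translation and the risk-factor effect cascade.

test_that("excise-tax arithmetic reproduces the worked elasticity examples", {
  # penny-per-ounce on a 12 oz, $1.00 beverage
  expect_equal(consumption_reduction_from_tax(tax_policy(0.01, 12, 1.00, -0.79)),
               0.79 * 0.12)
  expect_equal(consumption_reduction_from_tax(tax_policy(0.01, 12, 1.00, -1.00)),
               0.12)
  # a 32 oz container responds much more strongly
  expect_equal(consumption_reduction_from_tax(tax_policy(0.01, 32, 1.00, -0.79)),
               0.79 * 0.32)
  # no tax, no change
  expect_equal(consumption_reduction_from_tax(tax_policy(0, 12, 1.00, -0.79)), 0)
  # the reduction is capped at 1 regardless of tax size
  expect_equal(consumption_reduction_from_tax(tax_policy(5, 32, 0.5, -1)), 1)
  expect_error(tax_policy(0.01, 12, 0, -0.79), "pretax_price")
  expect_error(tax_policy(0.01, 12, 1, 0.5), "elasticity")
})

test_that("net energy change follows the three BMI scenarios", {
  p <- effect_parameters(kcal_per_serving = 150)
  expect_equal(net_calorie_change(-1, p, "moderate"), -150 * 0.61)
  expect_equal(net_calorie_change(-1, p, "strong"), -150)
  expect_equal(net_calorie_change(-1, p, "none"), 0)
  expect_error(net_calorie_change(-1, p, "extreme"), "unknown BMI scenario")
  expect_error(net_calorie_change(1, p, "moderate"), "non-positive")
})

test_that("calorie-to-BMI conversion follows the 3500 kcal/lb identity", {
  p <- default_effect_parameters()
  out <- calorie_to_bmi_delta(-91.5, "male", p)
  # independent arithmetic: lb = kcal/day * 365 / 3500; bmi = kg / height^2
  lb <- -91.5 * 365 / 3500
  expect_equal(out$d_weight_lb, lb)
  expect_equal(out$d_bmi, lb * 0.45359 / 1.76^2)
  expect_equal(out$d_bmi, -1.397, tolerance = 1e-3)
  # zero and linearity
  expect_equal(calorie_to_bmi_delta(0, "female", p)$d_bmi, 0)
  expect_equal(calorie_to_bmi_delta(-45.75, "male", p)$d_bmi, out$d_bmi / 2)
})

test_that("direct SBP effect uses sex-specific estimates with truncated bounds", {
  p <- default_effect_parameters()
  expect_equal(direct_sbp_delta(-1, "male", p, "main"), -0.78)
  expect_equal(direct_sbp_delta(-1, "female", p, "main"), -0.61)
  # women's lower CI bound (-0.27) is protective and truncates to zero,
  # leaving a minimal SBP effect in men only
  expect_equal(direct_sbp_delta(-1, "female", p, "min"), 0)
  expect_equal(direct_sbp_delta(-1, "male", p, "min"), -0.09)
  expect_equal(direct_sbp_delta(-1, "male", p, "max"), -1.47)
  expect_equal(direct_sbp_delta(-1, "female", p, "max"), -1.48)
  expect_equal(direct_sbp_delta(0, "female", p, "main"), 0)
})

test_that("truncation clamps protective draws at zero and keeps the rest", {
  expect_equal(truncate_protective(-0.27), 0)
  expect_equal(truncate_protective(0.09), 0.09)
  x <- c(0, 0.5, 2.3)
  expect_equal(truncate_protective(x), x)
})

test_that("BMI-mediated effects are linear in BMI with multiplicative diabetes RR", {
  p <- default_effect_parameters()
  m <- mediated_deltas(-1, "male", p)
  expect_equal(m$d_sbp, -1.43)
  expect_equal(m$d_ldl, -2.75)
  expect_equal(m$d_hdl, 1.55)
  expect_equal(m$diabetes_rr_component, 1 / 1.26)
  m0 <- mediated_deltas(0, "female", p)
  expect_equal(unlist(m0), c(d_sbp = 0, d_ldl = 0, d_hdl = 0,
                             diabetes_rr_component = 1))
  expect_equal(mediated_deltas(-2, "female", p)$diabetes_rr_component,
               1.30^-2)
})

test_that("log-scale mediation apportionment reproduces the adjusted RRs", {
  expect_equal(round(direct_diabetes_rr(1.14, 0.5), 2), 1.07)
  expect_equal(round(direct_diabetes_rr(1.59, 0.5), 2), 1.26)
  expect_equal(direct_diabetes_rr(1.35, 0), 1.35)
  expect_error(direct_diabetes_rr(-1, 0.5), "positive")
  # consistency: at 50% mediation the direct component squared is the total
  for (rr in c(1.05, 1.14, 1.35, 1.59, 2.4)) {
    expect_equal(direct_diabetes_rr(rr, 0.5)^2, rr)
  }
})

test_that("the composed cascade behaves correctly on single cells", {
  p <- default_effect_parameters()
  cell <- function(ssb, sex = "male") {
    data.frame(sex = sex, ssb_servings = ssb)
  }
  # a non-consumer is untouched by any scenario
  d0 <- apply_intervention(cell(0), scenario_spec(0.5, "strong", "max"), p)
  expect_equal(d0$diabetes_hazard_ratio, 1)
  expect_equal(unlist(d0[, c("d_servings", "d_kcal", "d_bmi", "d_sbp",
                             "d_ldl", "d_hdl")], use.names = FALSE),
               rep(0, 6))
  # 1 serving, 10% reduction, no BMI pathway, main bounds, men
  d <- apply_intervention(cell(1), scenario_spec(0.1, "none", "main"), p)
  expect_equal(d$d_sbp_direct, -0.078)
  expect_equal(d$d_bmi, 0)
  expect_equal(d$diabetes_hazard_ratio, sqrt(1.35)^-0.1)
  expect_equal(d$diabetes_hazard_ratio, 0.9851, tolerance = 1e-4)
})

test_that("a null intervention is the exact identity on every cell", {
  st <- fx_strata()
  d <- apply_intervention(st, scenario_spec(0, "moderate", "main"))
  expect_true(all(d$d_servings == 0))
  expect_true(all(d$d_sbp == 0 & d$d_ldl == 0 & d$d_hdl == 0))
  expect_true(all(d$diabetes_hazard_ratio == 1))
})

test_that("cascade magnitudes are monotone in reduction and BMI-effect strength", {
  p <- default_effect_parameters()
  cells <- data.frame(sex = rep(c("male", "female"), 3),
                      ssb_servings = c(0, 0.3, 0.7, 1, 1.6, 2.5))
  prev <- NULL
  for (red in c(0.1, 0.2, 0.5)) {
    d <- apply_intervention(cells, scenario_spec(red, "moderate", "main"), p)
    expect_true(all(d$diabetes_hazard_ratio > 0 & d$diabetes_hazard_ratio <= 1))
    if (!is.null(prev)) {
      expect_true(all(abs(d$d_sbp) >= abs(prev$d_sbp)))
      expect_true(all(d$diabetes_hazard_ratio <= prev$diabetes_hazard_ratio))
      expect_true(all(abs(d$d_bmi) >= abs(prev$d_bmi)))
    }
    prev <- d
  }
  # strong >= moderate >= none in BMI-mediated magnitude at fixed reduction
  ds <- lapply(c("strong", "moderate", "none"), function(b)
    apply_intervention(cells, scenario_spec(0.2, b, "main"), p))
  expect_true(all(abs(ds[[1]]$d_bmi) >= abs(ds[[2]]$d_bmi)))
  expect_true(all(abs(ds[[2]]$d_bmi) >= abs(ds[[3]]$d_bmi)))
  expect_true(all(ds[[1]]$diabetes_hazard_ratio <= ds[[2]]$diabetes_hazard_ratio))
  expect_true(all(ds[[2]]$diabetes_hazard_ratio <= ds[[3]]$diabetes_hazard_ratio))
})
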