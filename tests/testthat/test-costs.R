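# CPI adjustment, discounting, and the savings report.

flat_cost_params <- function(rate = 0, dm_cost = 6000, chd_cost = 10000,
                             chd_years = 5) {
  cost_parameters(diabetes_cost_by_age = rep(dm_cost, 6),
                  chd_cost_by_age = rep(chd_cost, 6),
                  cost_dollar_year = 2012,
                  cpi_series = c("2010" = 1, "2012" = 1),
                  discount_rate = rate,
                  chd_years_per_event = chd_years)
}

fake_result <- function(dm_py_averted = 0, chd_py_averted = 0,
                        dm_attrib_averted = rep(0, 10), params = NULL) {
  years <- 2013:2022
  mat <- function(total) {
    m <- matrix(0, 10, 6, dimnames = list(years, NULL))
    m[1, 3] <- total
    m
  }
  zero <- matrix(0, 10, 6, dimnames = list(years, NULL))
  arm <- function(dm, chd, attrib) {
    list(py_dm_band = dm, py_chd_band = chd,
         per_year = data.frame(year = years, dm_attrib_chd = attrib))
  }
  base_dm <- mat(100); base_chd <- mat(100)
  int_dm <- base_dm; int_dm[1, 3] <- 100 - dm_py_averted
  int_chd <- base_chd; int_chd[1, 3] <- 100 - chd_py_averted
  structure(list(baseline = arm(base_dm, base_chd, dm_attrib_averted * 0 + 1),
                 intervention = arm(int_dm, int_chd, 1 - dm_attrib_averted)),
            class = "scenario_result")
}

test_that("CPI adjustment rescales by the index ratio", {
  p <- cost_parameters()
  expect_equal(cpi_adjust(100, 2012, p), 100)
  p2 <- cost_parameters(cpi_series = c("2000" = 200, "2010" = 400,
                                       "2012" = 800))
  expect_equal(cpi_adjust(50, 2010, p2), 100)
  p3 <- cost_parameters(cpi_series = c("2010" = 400, "2012" = 425.6))
  expect_equal(cpi_adjust(100, 2010, p3), 106.4)
  expect_error(cpi_adjust(100, 1990, p), "CPI series")
})

test_that("discounting matches the closed form and is monotone in horizon", {
  p <- cost_parameters(discount_rate = 0.03)
  expect_equal(discount_stream(c("2013" = 100, "2014" = 100), p),
               100 + 100 / 1.03)
  expect_equal(round(discount_stream(c("2013" = 100, "2014" = 100), p), 2),
               197.09)
  # r = 0 reduces to a plain sum
  p0 <- cost_parameters(discount_rate = 0)
  x <- c("2013" = 10, "2015" = 20, "2020" = 30)
  expect_equal(discount_stream(x, p0), 60)
  # a single payment loses value the further out it sits
  pv <- vapply(2014:2022, function(y)
    discount_stream(stats::setNames(100, y), p), numeric(1))
  expect_true(all(diff(pv) < 0))
  # discounted PV of a positive stream never exceeds its plain sum
  expect_lt(discount_stream(x, p), sum(x))
  expect_error(discount_stream(c("2000" = 5), p), "base year")
})

test_that("savings follow averted person-state-years at the unit costs", {
  # 5 averted diabetic person-years at $6,000/yr, r = 0, flat CPI
  rep0 <- savings_report(fake_result(dm_py_averted = 5), flat_cost_params())
  expect_equal(rep0$savings_usd[rep0$category == "diabetes_direct"], 30000)
  expect_equal(rep0$savings_usd[rep0$category == "total_chd"], 0)
  # one averted diabetes-attributable CHD event in year one, 5 years of care
  rep1 <- savings_report(fake_result(dm_attrib_averted = c(1, rep(0, 9))),
                         flat_cost_params())
  expect_equal(rep1$savings_usd[rep1$category == "diabetes_related_chd"],
               5 * 10000)
  # zero averted anything = zero savings in all categories
  rep2 <- savings_report(fake_result(), flat_cost_params())
  expect_equal(rep2$savings_usd, rep(0, 3))
})

test_that("savings are linear in unit costs and invariant to CPI re-basing", {
  st <- fx_strata()
  hz <- fx_calibrated()
  res <- run_scenario(st, scenario_spec(0.2, "moderate", "main"), hz)
  p1 <- cost_parameters()
  p2 <- cost_parameters(diabetes_cost_by_age = 2 * p1$diabetes_cost_by_age,
                        chd_cost_by_age = 2 * p1$chd_cost_by_age)
  s1 <- savings_report(res, p1)
  s2 <- savings_report(res, p2)
  expect_equal(s2$savings_usd, 2 * s1$savings_usd)
  # re-basing the CPI rescales every category by one common factor
  p3 <- cost_parameters(cpi_series = 2 * p1$cpi_series)
  s3 <- savings_report(res, p3)
  expect_equal(s3$savings_usd, s1$savings_usd)
  p4 <- cost_parameters(base_dollar_year = 2013)
  s4 <- savings_report(res, p4)
  ratio <- s4$savings_usd / s1$savings_usd
  expect_equal(ratio, rep(ratio[1], 3))
})
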