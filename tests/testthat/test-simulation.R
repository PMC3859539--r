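# Annual-cycle state-transition engine: closed forms, conservation,
# calibration, and agreement with the individual-level microsimulation.

one_stratum <- function(n = 1000, age = 50, sex = "male", state = "well") {
  st <- data.frame(age = age, sex = sex, subgroup = "all", ssb_bin = 1L,
                   ssb_servings = 0.5, bmi = 27, sbp = 120, ldl = 130,
                   hdl = 50, smoking = 0,
                   n_well = 0, n_diabetes = 0, n_chd = 0,
                   n_diabetes_and_chd = 0, n_dead_chd = 0, n_dead_other = 0)
  st[[paste0("n_", state)]] <- n
  st
}

test_that("with all hazards off a cycle only ages the population", {
  st <- fx_strata()
  out <- step_year(st, fx_zero_hazards())
  expect_equal(out$strata$age, st$age + 1L)
  expect_equal(out$strata$n_well, st$n_well)
  expect_equal(out$strata$n_diabetes, st$n_diabetes)
  expect_equal(out$tally$incident_diabetes, 0)
  expect_equal(out$tally$all_deaths, 0)
  expect_equal(out$tally$person_years, alive_total(st))
})

test_that("single-cell diabetes incidence matches its closed form", {
  hz <- hazard_model(multipliers = list(diabetes = 1, chd = 0, mi = 0,
                                        chd_mortality = 0, other_mortality = 0))
  st <- one_stratum(n = 1000, age = 50, sex = "male")
  h <- hz$diabetes_rate50  # age 50 male: the raw rate
  out <- step_year(st, hz)
  expect_equal(out$tally$incident_diabetes, 1000 * (1 - exp(-h)))
  # the diabetes hazard ratio from an intervention scales the hazard itself
  delta <- tibble::tibble(d_sbp = 0, d_ldl = 0, d_hdl = 0,
                          diabetes_hazard_ratio = 0.8)
  out2 <- step_year(st, hz, delta)
  expect_equal(out2$tally$incident_diabetes, 1000 * (1 - exp(-0.8 * h)))
})

test_that("persons are conserved across alive and dead states every year", {
  st <- fx_strata()
  hz <- fx_calibrated()
  n0 <- total_persons(st)
  cur <- st
  for (y in 1:10) {
    cur <- step_year(cur, hz)$strata
    expect_equal(total_persons(cur), n0)
    expect_true(all(cur[paste0("n_", c("well", "diabetes", "chd",
                                       "diabetes_and_chd", "dead_chd",
                                       "dead_other"))] >= -1e-9))
  }
})

test_that("expected events scale linearly with hazards in the rare-event regime", {
  st <- fx_strata()
  eps <- 1e-3
  hz1 <- hazard_model(multipliers = list(diabetes = eps, chd = eps, mi = 1,
                                         chd_mortality = eps,
                                         other_mortality = eps))
  hz2 <- hazard_model(multipliers = list(diabetes = 2 * eps, chd = 2 * eps,
                                         mi = 1, chd_mortality = 2 * eps,
                                         other_mortality = 2 * eps))
  c1 <- run_cohort(st, hz1)$cumulative
  c2 <- run_cohort(st, hz2)$cumulative
  for (oc in c("incident_diabetes", "incident_chd", "all_deaths")) {
    expect_equal(c2[[oc]] / c1[[oc]], 2, tolerance = 0.02)
  }
})

test_that("calibration to a run's own output returns unit multipliers", {
  st <- fx_strata()
  hz <- default_hazard_model()
  own <- as.list(run_cohort(st, hz)$cumulative[
    c("incident_diabetes", "incident_chd", "total_mi", "chd_deaths",
      "all_deaths")])
  cal <- calibrate_baseline(st, hz, own)
  expect_equal(unlist(cal$multipliers), unlist(hz$multipliers),
               tolerance = 1e-6)
})

test_that("doubled targets yield near-doubled multipliers at small hazards", {
  st <- fx_strata()
  hz <- hazard_model(multipliers = list(diabetes = 0.05, chd = 0.05, mi = 0.05,
                                        chd_mortality = 0.05,
                                        other_mortality = 0.05))
  own <- run_cohort(st, hz)$cumulative
  doubled <- as.list(2 * own[c("incident_diabetes", "incident_chd",
                               "total_mi", "chd_deaths", "all_deaths")])
  cal <- calibrate_baseline(st, hz, doubled)
  expect_equal(unlist(cal$multipliers) / unlist(hz$multipliers),
               c(diabetes = 2, chd = 2, mi = 2, chd_mortality = 2,
                 other_mortality = 2),
               tolerance = 0.1)
})

test_that("baseline counts calibrate to the anticipated counts within 1%", {
  st <- fx_strata()
  persons <- alive_total(st)
  targets <- calibration_targets(persons)
  hz <- fx_calibrated()
  cum <- run_cohort(st, hz)$cumulative
  for (oc in c("incident_diabetes", "incident_chd", "total_mi",
               "chd_deaths", "all_deaths")) {
    expect_lt(abs(cum[[oc]] - targets[[oc]]) / targets[[oc]], 0.01)
  }
})

test_that("event-rate differences per million person-years are computed and signed correctly", {
  st <- fx_strata()
  hz <- fx_calibrated()
  res <- run_scenario(st, scenario_spec(0.1, "moderate", "main"), hz)
  rates <- rate_difference_per_million_py(res)
  # fewer events under the intervention show as a positive drop
  expect_true(all(rates[c("incident_diabetes", "incident_chd",
                          "total_mi", "chd_deaths")] > 0))
  # hand arithmetic on the definition
  py <- res$baseline$cumulative[["person_years"]]
  d <- res$baseline$cumulative[["incident_diabetes"]] -
    res$intervention$cumulative[["incident_diabetes"]]
  expect_equal(rates[["incident_diabetes"]], d / py * 1e6)
})

test_that("a null intervention produces exactly zero differences", {
  st <- fx_strata()
  hz <- fx_calibrated()
  res <- run_scenario(st, scenario_spec(0, "moderate", "main"), hz)
  expect_equal(unname(res$difference), rep(0, 5))
  expect_equal(unname(rate_difference_per_million_py(res)), rep(0, 5))
})

test_that("the intervention arm never exceeds baseline event counts", {
  st <- fx_strata()
  hz <- fx_calibrated()
  for (bnd in c("min", "main", "max")) {
    res <- run_scenario(st, scenario_spec(0.2, "moderate", bnd), hz)
    expect_true(all(res$difference[c("incident_diabetes", "incident_chd",
                                     "total_mi", "chd_deaths")] <= 1e-9))
  }
})

test_that("percent reductions are invariant to uniform population scaling", {
  st <- fx_strata()
  hz <- fx_calibrated()
  res1 <- run_scenario(st, scenario_spec(0.1, "moderate", "main"), hz)
  st10 <- st
  for (col in paste0("n_", c("well", "diabetes", "chd", "diabetes_and_chd")))
    st10[[col]] <- st10[[col]] * 10
  res10 <- run_scenario(st10, scenario_spec(0.1, "moderate", "main"), hz)
  expect_equal(res10$percent, res1$percent, tolerance = 1e-12)
})

test_that("cohort solver and seeded microsimulation agree within 3 SEs", {
  pop <- fx_population(n = 10000, seed = 11)
  st <- fx_strata(n = 10000, seed = 11)
  hz <- fx_calibrated(n = 10000, seed = 11)
  sc <- scenario_spec(0.5, "strong", "main")
  coh <- run_scenario(st, sc, hz)
  micro_b <- run_microsim(pop, hz, NULL, seed = 301)
  micro_i <- run_microsim(pop, hz, sc, seed = 302)
  for (oc in c("incident_diabetes", "incident_chd", "total_mi",
               "chd_deaths", "all_deaths")) {
    eb <- coh$baseline$cumulative[[oc]]
    ei <- coh$intervention$cumulative[[oc]]
    # Poisson SE bounds the Bernoulli-sum variance from above
    expect_lt(abs(micro_b$cumulative[[oc]] - eb), 3 * sqrt(eb))
    expect_lt(abs(micro_i$cumulative[[oc]] - ei), 3 * sqrt(ei))
  }
  expect_equal(micro_b$cumulative[["person_years"]],
               coh$baseline$cumulative[["person_years"]],
               tolerance = 0.02)
})
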