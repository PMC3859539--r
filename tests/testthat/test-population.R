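# Synthetic population generator: determinism, marginal fidelity, validation.

test_that("identical config and seed give a bit-identical population", {
  cfg <- population_config(total_count = 5000, seed = 123)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_population(population_config(total_count = 5000, seed = 124))
  expect_false(identical(as.data.frame(p1), as.data.frame(p3)))
})

test_that("a zero-count config yields an empty population without error", {
  pop <- generate_population(population_config(total_count = 0))
  expect_equal(nrow(pop), 0)
  expect_true(all(c("age", "sex", "ssb_servings", "health_state", "count")
                  %in% names(pop)))
})

test_that("infeasible configs are rejected naming the offending field", {
  expect_error(population_config(diabetes_prevalence = 1.5),
               "diabetes_prevalence")
  expect_error(population_config(sex_fractions = c(male = 0.7, female = 0.6)),
               "sex_fractions")
  expect_error(population_config(age_range = c(60, 40)), "age_range")
  expect_error(population_config(ssb_shape = -1), "ssb_shape")
})

test_that("every targeted marginal is matched at large n", {
  pop <- fx_population(n = 1e5, seed = 2024)
  report <- validate_marginals(pop)
  expect_true(all(report$pass),
              info = paste(report$marginal[!report$pass], collapse = ", "))
})

test_that("realised subgroup prevalence and consumption track their targets", {
  pop <- fx_population(n = 2e5, seed = 7, subgroup = "african_american")
  dm <- sum(pop$count[pop$health_state %in% c("diabetes", "diabetes_and_chd")]) /
    sum(pop$count)
  # binomial draw at n = 200,000: realised prevalence within 0.5 pp of 0.115
  expect_lt(abs(dm - 0.115), 0.005)
  pop_li <- fx_population(n = 1e5, seed = 8, subgroup = "low_income")
  m <- weighted.mean(pop_li$ssb_servings, pop_li$count)
  expect_lt(abs(m - 0.70) / 0.70, 0.02)
})

test_that("generated mean consumption preserves the subgroup ordering", {
  means <- vapply(c("white", "african_american", "mexican_american",
                    "low_income"), function(sg) {
    pop <- fx_population(n = 3e4, seed = 31, subgroup = sg)
    weighted.mean(pop$ssb_servings, pop$count)
  }, numeric(1))
  expect_true(means[["low_income"]] > means[["mexican_american"]])
  expect_true(means[["mexican_american"]] > means[["african_american"]])
  expect_true(means[["african_american"]] > means[["white"]])
})

test_that("validate_marginals reports a forced failure and honours tolerance 0", {
  pop <- fx_population()
  broken <- pop
  broken$ssb_servings <- 0
  report <- validate_marginals(broken, attr(pop, "config"))
  expect_false(report$pass[report$marginal == "ssb_mean"])
  # a zero tolerance fails on any stochastic draw
  strict <- validate_marginals(pop, attr(pop, "config"),
                               tolerances = list(mean_rel = 0, prev_abs = 0))
  expect_false(all(strict$pass))
})

test_that("populations round-trip through CSV with config sidecar", {
  pop <- generate_population(population_config(total_count = 2000, seed = 5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_population(pop, path)
  back <- read_population(path)
  a <- as.data.frame(back); b <- as.data.frame(pop)
  attr(a, "config") <- NULL; attr(b, "config") <- NULL
  expect_equal(a, b)
  expect_equal(attr(back, "config")$seed, 5)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("the strata view conserves counts and carries all states", {
  pop <- fx_population()
  st <- as_strata(pop)
  expect_equal(sum(st[paste0("n_", c("well", "diabetes", "chd",
                                     "diabetes_and_chd"))]),
               sum(pop$count))
  expect_true(all(st$n_dead_chd == 0 & st$n_dead_other == 0))
})
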