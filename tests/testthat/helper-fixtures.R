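# Shared fixtures, memoised so expensive pieces (population generation,
# calibration) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

fx_population <- function(n = 20000, seed = 11, subgroup = "all") {
  fx_memo(sprintf("pop_%s_%d_%d", subgroup, n, seed), function() {
    generate_population(population_config(total_count = n, seed = seed,
                                          subgroup = subgroup))
  })
}

fx_strata <- function(n = 20000, seed = 11, subgroup = "all") {
  fx_memo(sprintf("st_%s_%d_%d", subgroup, n, seed), function() {
    as_strata(fx_population(n, seed, subgroup))
  })
}

# Hazards calibrated to the shipped anticipated counts, scaled to n persons.
fx_calibrated <- function(n = 20000, seed = 11, subgroup = "all",
                          diabetes_scale = 1) {
  fx_memo(sprintf("hz_%s_%d_%d_%g", subgroup, n, seed, diabetes_scale),
          function() {
    st <- fx_strata(n, seed, subgroup)
    persons <- sum(st[paste0("n_", c("well", "diabetes", "chd",
                                     "diabetes_and_chd"))])
    calibrate_baseline(st, default_hazard_model(),
                       calibration_targets(persons,
                                           diabetes_scale = diabetes_scale))
  })
}

# Hazard model with all event intensities switched off.
fx_zero_hazards <- function() {
  hazard_model(multipliers = list(diabetes = 0, chd = 0, mi = 0,
                                  chd_mortality = 0, other_mortality = 0))
}

alive_total <- function(st) {
  sum(st$n_well + st$n_diabetes + st$n_chd + st$n_diabetes_and_chd)
}

total_persons <- function(st) {
  alive_total(st) + sum(st$n_dead_chd + st$n_dead_other)
}
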