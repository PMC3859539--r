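# Annual-cycle state-transition engine (expected-value cohort solver) and a
# seeded individual-level microsimulation used as its stochastic cross-check.

identity_delta <- function(n) {
  tibble::tibble(d_sbp = rep(0, n), d_ldl = rep(0, n), d_hdl = rep(0, n),
                 diabetes_hazard_ratio = rep(1, n))
}

n_bands <- function() length(AGE_BAND_BREAKS)

band_sums <- function(x, band) {
  out <- numeric(n_bands())
  s <- rowsum(x, band)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Advance the population one annual cycle
#'
#' Event order within a cycle: diabetes incidence, CHD incidence (a fixed
#' fraction of which are MIs) plus recurrent MI among the pre-existing CHD
#' pool, CHD death (acute MI case fatality plus chronic CHD mortality),
#' non-CVD death (with a diabetes multiplier), then ageing by one year.
#' Competing risks are resolved sequentially; each hazard `h` becomes an
#' annual probability `1 - exp(-h)`. Person-years use a full-year convention
#' for everyone alive at the start of the cycle. Total persons are conserved
#' across alive + dead states. Dead states receive no risk-factor updates.
#'
#' @param strata A strata view from [as_strata()].
#' @param hz A [hazard_model()].
#' @param delta Optional per-stratum intervention deltas
#'   (from [apply_intervention()]); `NULL` means the baseline arm.
#' @return A list with `strata` (advanced one year) and `tally` (a one-row
#'   data frame of the cycle's events, person-years, and cost-accounting
#'   person-state-year vectors by age band).
#' @export
step_year <- function(strata, hz, delta = NULL) {
  n <- nrow(strata)
  if (is.null(delta)) delta <- identity_delta(n)
  if (nrow(delta) != n)
    stopf("'delta' must have one row per stratum (%d != %d)", nrow(delta), n)
  if (any(delta$diabetes_hazard_ratio <= 0))
    stopf("diabetes hazard ratios must be positive (first offending stratum row %d)",
          which(delta$diabetes_hazard_ratio <= 0)[1])
  m <- hz$multipliers
  age <- strata$age; sex <- strata$sex
  band <- age_band(age)

  n_well <- strata$n_well; n_dm <- strata$n_diabetes
  n_chd <- strata$n_chd; n_dmchd <- strata$n_diabetes_and_chd

  alive0 <- n_well + n_dm + n_chd + n_dmchd
  py <- sum(alive0)
  py_dm_band <- band_sums(n_dm, band)
  py_chd_band <- band_sums(n_chd + n_dmchd, band)

  # intervention-adjusted risk factors (alive states only, by construction)
  sbp <- strata$sbp + delta$d_sbp
  ldl <- strata$ldl + delta$d_ldl
  hdl <- strata$hdl + delta$d_hdl

  # 1. diabetes incidence
  h_dm <- diabetes_hazard_at(hz, age, sex) * m$diabetes *
    delta$diabetes_hazard_ratio
  if (any(h_dm < 0))
    stopf("negative diabetes hazard in stratum row %d", which(h_dm < 0)[1])
  p_dm <- 1 - exp(-h_dm)
  f_well <- n_well * p_dm
  f_chd <- n_chd * p_dm
  n_well <- n_well - f_well; n_dm <- n_dm + f_well
  n_chd <- n_chd - f_chd; n_dmchd <- n_dmchd + f_chd
  incident_diabetes <- sum(f_well) + sum(f_chd)

  # 2. CHD incidence / MI
  h0 <- chd_hazard_at(hz, age, sex, sbp, ldl, hdl, strata$smoking) * m$chd
  if (any(h0 < 0))
    stopf("negative CHD hazard in stratum row %d", which(h0 < 0)[1])
  h1 <- h0 * exp(hz$chd_diabetes_log_hr)
  p0 <- 1 - exp(-h0); p1 <- 1 - exp(-h1)
  pool <- n_chd + n_dmchd  # recurrent-MI pool: CHD history before this year's events
  e0 <- n_well * p0
  e1 <- n_dm * p1
  incident_chd <- sum(e0) + sum(e1)
  # excess fraction (RR-1)/RR of diabetic-cell events attributable to diabetes
  dm_attrib_chd <- sum(e1) * (1 - exp(-hz$chd_diabetes_log_hr))
  mi_frac <- min(hz$mi_fraction * m$mi, 0.95)
  new_mi <- (e0 + e1) * mi_frac
  rec_mi <- pool * (1 - exp(-hz$recurrent_mi_hazard * m$mi))
  total_mi_row <- new_mi + rec_mi
  n_well <- n_well - e0; n_chd <- n_chd + e0
  n_dm <- n_dm - e1; n_dmchd <- n_dmchd + e1

  # 3. CHD death: acute case fatality on MIs + chronic CHD mortality
  cf <- case_fatality_at(hz, age, m$chd_mortality)
  acute <- total_mi_row * cf
  p_chronic <- 1 - exp(-hz$chd_chronic_mortality * m$chd_mortality)
  chd_pool <- n_chd + n_dmchd
  cd <- pmin(acute + chd_pool * p_chronic, chd_pool)
  share <- ifelse(chd_pool > 0, cd / chd_pool, 0)
  n_dead_chd <- strata$n_dead_chd + cd
  n_chd <- n_chd * (1 - share); n_dmchd <- n_dmchd * (1 - share)
  chd_deaths <- sum(cd)

  # 4. non-CVD death (diabetes multiplier on diabetic states)
  h_mort <- other_mortality_at(hz, age, sex) * m$other_mortality
  p_o0 <- 1 - exp(-h_mort)
  p_o1 <- 1 - exp(-h_mort * hz$diabetes_mortality_mult)
  d_well <- n_well * p_o0; d_chd <- n_chd * p_o0
  d_dm <- n_dm * p_o1; d_dmchd <- n_dmchd * p_o1
  n_well <- n_well - d_well; n_chd <- n_chd - d_chd
  n_dm <- n_dm - d_dm; n_dmchd <- n_dmchd - d_dmchd
  n_dead_other <- strata$n_dead_other + d_well + d_chd + d_dm + d_dmchd
  other_deaths <- sum(d_well) + sum(d_chd) + sum(d_dm) + sum(d_dmchd)

  # 5. age one year
  out <- strata
  out$age <- age + 1L
  out$n_well <- n_well; out$n_diabetes <- n_dm
  out$n_chd <- n_chd; out$n_diabetes_and_chd <- n_dmchd
  out$n_dead_chd <- n_dead_chd; out$n_dead_other <- n_dead_other

  tally <- data.frame(incident_diabetes = incident_diabetes,
                      incident_chd = incident_chd,
                      total_mi = sum(total_mi_row),
                      chd_deaths = chd_deaths,
                      all_deaths = chd_deaths + other_deaths,
                      person_years = py,
                      py_diabetes = sum(py_dm_band),
                      py_chd = sum(py_chd_band),
                      dm_attrib_chd = dm_attrib_chd)
  list(strata = out, tally = tally,
       py_dm_band = py_dm_band, py_chd_band = py_chd_band)
}

#' Run the expected-value cohort solver for several annual cycles
#'
#' @param strata A strata view from [as_strata()].
#' @param hz A [hazard_model()].
#' @param delta Optional intervention deltas, held fixed across cycles
#'   (steady-state intervention).
#' @param years Number of annual cycles (default 10).
#' @param start_year Calendar year of the first cycle (default 2013).
#' @return An object of class `outcome_tally`: a list with `per_year` (one
#'   row per cycle), `cumulative` (named totals), and `py_dm_band` /
#'   `py_chd_band` (years x age-band person-state-year matrices used by the
#'   cost model).
#' @export
run_cohort <- function(strata, hz, delta = NULL, years = 10,
                       start_year = 2013) {
  tallies <- vector("list", years)
  dm_band <- matrix(0, years, n_bands())
  chd_band <- matrix(0, years, n_bands())
  st <- strata
  for (t in seq_len(years)) {
    stp <- step_year(st, hz, delta)
    st <- stp$strata
    tallies[[t]] <- cbind(year = start_year + t - 1L, stp$tally)
    dm_band[t, ] <- stp$py_dm_band
    chd_band[t, ] <- stp$py_chd_band
  }
  per_year <- tibble::as_tibble(do.call(rbind, tallies))
  cum <- colSums(per_year[, c(OUTCOMES, "person_years", "py_diabetes",
                              "py_chd", "dm_attrib_chd")])
  rownames(dm_band) <- rownames(chd_band) <- start_year + seq_len(years) - 1L
  structure(list(per_year = per_year, cumulative = cum,
                 py_dm_band = dm_band, py_chd_band = chd_band,
                 final_strata = st),
            class = "outcome_tally")
}

#' Run paired baseline and intervention arms
#'
#' Runs the cohort solver under identity deltas (baseline) and under the
#' scenario's intervention deltas, and reports per-outcome differences
#' (intervention minus baseline; negative values are averted events) and
#' percent changes relative to the baseline anticipated counts.
#'
#' @param population An `ssb_population` (or a strata view).
#' @param scenario A [scenario_spec()].
#' @param hz A (typically calibrated) [hazard_model()].
#' @param params An [effect_parameters()] object.
#' @param years,start_year Simulation horizon.
#' @return An object of class `scenario_result`: list with `scenario`,
#'   `anticipated` (baseline cumulative counts), `baseline` and
#'   `intervention` tallies, `difference` and `percent` per outcome.
#' @export
run_scenario <- function(population, scenario, hz,
                         params = default_effect_parameters(),
                         years = 10, start_year = 2013) {
  st <- if (inherits(population, "ssb_population")) as_strata(population)
        else population
  delta <- apply_intervention(st, scenario, params)
  baseline <- run_cohort(st, hz, NULL, years, start_year)
  intervention <- run_cohort(st, hz, delta, years, start_year)
  difference <- intervention$cumulative[OUTCOMES] - baseline$cumulative[OUTCOMES]
  percent <- 100 * difference / baseline$cumulative[OUTCOMES]
  structure(list(scenario = scenario,
                 anticipated = baseline$cumulative[OUTCOMES],
                 baseline = baseline, intervention = intervention,
                 difference = difference, percent = percent),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("SSB reduction scenario: %.0f%% reduction, %s BMI effect, %s bounds\n",
              100 * x$scenario$reduction_fraction, x$scenario$bmi_scenario,
              x$scenario$bound))
  df <- data.frame(outcome = OUTCOMES,
                   anticipated = round(x$anticipated),
                   difference = round(x$difference, 1),
                   percent = round(x$percent, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Outcome rate differences per million person-years
#'
#' `(baseline - intervention) / baseline person-years * 1e6` per outcome:
#' positive values are drops in the event rate under the intervention.
#' Baseline-arm person-years are the denominator.
#'
#' @param result A `scenario_result`.
#' @return Named numeric vector of rate drops per million person-years.
#' @export
rate_difference_per_million_py <- function(result) {
  py <- result$baseline$cumulative[["person_years"]]
  if (py <= 0) stopf("baseline person-years must be positive")
  (result$baseline$cumulative[OUTCOMES] -
     result$intervention$cumulative[OUTCOMES]) / py * 1e6
}

# --- individual-level microsimulation (stochastic cross-check) ------------

expand_individuals <- function(population) {
  cnt <- round(population$count)
  idx <- rep(seq_len(nrow(population)), cnt)
  ind <- as.data.frame(population)[idx, c("age", "sex", "ssb_servings", "bmi",
                                          "sbp", "ldl", "hdl", "smoking",
                                          "health_state")]
  rownames(ind) <- NULL
  ind$smoker <- as.numeric(stats::runif(nrow(ind)) < ind$smoking)
  ind
}

#' Seeded individual-level microsimulation
#'
#' Simulates the same annual-cycle event structure as [step_year()] with
#' per-person Bernoulli draws, as an independent stochastic cross-check of
#' the expected-value cohort solver (intended for populations of up to a few
#' tens of thousands of persons).
#'
#' @param population An `ssb_population`.
#' @param hz A [hazard_model()].
#' @param scenario Optional [scenario_spec()]; `NULL` simulates the baseline.
#' @param params An [effect_parameters()] object.
#' @param years,start_year Simulation horizon.
#' @param seed Integer RNG seed.
#' @return A list with `per_year` and `cumulative` tallies matching the
#'   cohort solver's outcome columns.
#' @export
run_microsim <- function(population, hz, scenario = NULL,
                         params = default_effect_parameters(),
                         years = 10, start_year = 2013, seed = 1L) {
  set.seed(seed)
  ind <- expand_individuals(population)
  n <- nrow(ind)
  m <- hz$multipliers
  if (!is.null(scenario)) {
    d <- apply_intervention(ind, scenario, params)
    ind$sbp <- ind$sbp + d$d_sbp
    ind$ldl <- ind$ldl + d$d_ldl
    ind$hdl <- ind$hdl + d$d_hdl
    dm_hr <- d$diabetes_hazard_ratio
  } else {
    dm_hr <- rep(1, n)
  }
  state <- ind$health_state
  tallies <- vector("list", years)
  for (t in seq_len(years)) {
    alive <- state %in% ALIVE_STATES
    py <- sum(alive)
    # 1. diabetes incidence
    h_dm <- diabetes_hazard_at(hz, ind$age, ind$sex) * m$diabetes * dm_hr
    p_dm <- 1 - exp(-h_dm)
    at_risk <- alive & state %in% c("well", "chd")
    inc_dm <- at_risk & stats::runif(n) < p_dm
    state[inc_dm & state == "well"] <- "diabetes"
    state[inc_dm & state == "chd"] <- "diabetes_and_chd"
    # 2. CHD incidence / MI; recurrent pool = CHD history predating this cycle
    pool <- alive & state %in% c("chd", "diabetes_and_chd")
    h0 <- chd_hazard_at(hz, ind$age, ind$sex, ind$sbp, ind$ldl, ind$hdl,
                        ind$smoker) * m$chd
    h_chd <- ifelse(state %in% c("diabetes", "diabetes_and_chd"),
                    h0 * exp(hz$chd_diabetes_log_hr), h0)
    at_risk_chd <- alive & state %in% c("well", "diabetes")
    new_chd <- at_risk_chd & stats::runif(n) < (1 - exp(-h_chd))
    state[new_chd & state == "well"] <- "chd"
    state[new_chd & state == "diabetes"] <- "diabetes_and_chd"
    mi_frac <- min(hz$mi_fraction * m$mi, 0.95)
    new_mi <- new_chd & stats::runif(n) < mi_frac
    rec_mi <- pool & stats::runif(n) < (1 - exp(-hz$recurrent_mi_hazard * m$mi))
    had_mi <- new_mi | rec_mi
    # 3. CHD death
    cf <- case_fatality_at(hz, ind$age, m$chd_mortality)
    acute_death <- had_mi & stats::runif(n) < cf
    chronic_pool <- (state %in% c("chd", "diabetes_and_chd")) & !acute_death &
      alive
    p_chronic <- 1 - exp(-hz$chd_chronic_mortality * m$chd_mortality)
    chronic_death <- chronic_pool & stats::runif(n) < p_chronic
    chd_dead <- acute_death | chronic_death
    state[chd_dead] <- "dead_chd"
    # 4. non-CVD death
    h_mort <- other_mortality_at(hz, ind$age, ind$sex) * m$other_mortality
    h_mort <- ifelse(state %in% c("diabetes", "diabetes_and_chd"),
                     h_mort * hz$diabetes_mortality_mult, h_mort)
    still_alive <- state %in% ALIVE_STATES
    other_dead <- still_alive & stats::runif(n) < (1 - exp(-h_mort))
    state[other_dead] <- "dead_other"
    # 5. age
    ind$age <- ind$age + 1L
    tallies[[t]] <- data.frame(
      year = start_year + t - 1L,
      incident_diabetes = sum(inc_dm),
      incident_chd = sum(new_chd),
      total_mi = sum(had_mi),
      chd_deaths = sum(chd_dead),
      all_deaths = sum(chd_dead) + sum(other_dead),
      person_years = py)
  }
  per_year <- tibble::as_tibble(do.call(rbind, tallies))
  cum <- colSums(per_year[, c(OUTCOMES, "person_years")])
  list(per_year = per_year, cumulative = cum)
}
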