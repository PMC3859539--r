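#' Ten-year anticipated case counts used as calibration targets
#'
#' Default targets are the anticipated 2013-2022 counts for the reference
#' adult population before any consumption change: 666,000 incident diabetes
#' cases, 1,140,000 incident CHD, 560,000 total MI, 336,000 CHD deaths and
#' 1,668,000 deaths from any cause, scaled linearly from the
#' `reference_population` to the synthetic population actually simulated.
#' For subgroup runs, `diabetes_scale` additionally scales the diabetes
#' target by the subgroup-to-statewide prevalence ratio (subgroup baseline
#' incidence levels are not published; prevalence is used as its proxy).
#'
#' @param population_size Persons in the simulated population.
#' @param reference_population Adults the default counts refer to
#'   (default 16 million, an adult 35+ population of California scale).
#' @param diabetes_scale Extra multiplier on the diabetes target.
#' @param base Named list of the five reference counts.
#' @return A named list of class `calibration_targets`.
#' @export
calibration_targets <- function(population_size,
                                reference_population = 16e6,
                                diabetes_scale = 1,
                                base = list(incident_diabetes = 666000,
                                            incident_chd = 1140000,
                                            total_mi = 560000,
                                            chd_deaths = 336000,
                                            all_deaths = 1668000)) {
  check_number(population_size, "population_size", lower = 1)
  check_number(reference_population, "reference_population", lower = 1)
  check_number(diabetes_scale, "diabetes_scale", lower = 1e-9)
  if (!all(OUTCOMES %in% names(base)) || any(unlist(base[OUTCOMES]) <= 0))
    stopf("'base' must hold positive counts for %s",
          paste(OUTCOMES, collapse = ", "))
  s <- population_size / reference_population
  out <- lapply(base[OUTCOMES], function(x) x * s)
  out$incident_diabetes <- out$incident_diabetes * diabetes_scale
  structure(out, class = "calibration_targets")
}

#' Calibrate baseline hazards to anticipated case counts
#'
#' Finds per-outcome scalar multipliers on the baseline hazards such that the
#' simulated 10-year baseline counts match the targets within `tol` relative
#' error. The five multipliers map one-to-one onto outcomes (diabetes
#' incidence, CHD incidence, MI, CHD mortality, non-CVD mortality); since
#' each count responds almost linearly to its own multiplier, a damped
#' proportional fixed-point iteration (each sweep is one deterministic cohort
#' run) converges in a handful of sweeps despite cross-outcome interactions.
#' The `all_deaths` target is matched through the non-CVD mortality
#' multiplier after accounting for the CHD deaths already produced.
#'
#' @param population An `ssb_population` (or strata view).
#' @param hz A [hazard_model()] to rescale.
#' @param targets A [calibration_targets()] list.
#' @param tol Relative tolerance (default 1%); iteration stops at `tol / 2`
#'   to leave margin.
#' @param max_iter Maximum sweeps before aborting with the residuals.
#' @param years Simulation horizon used for calibration.
#' @return The hazard model with calibrated `multipliers`; the final
#'   relative residuals are attached as `attr(, "residuals")` and the sweep
#'   count as `attr(, "iterations")`.
#' @export
calibrate_baseline <- function(population, hz, targets, tol = 0.01,
                               max_iter = 60, years = 10) {
  st <- if (inherits(population, "ssb_population")) as_strata(population)
        else population
  if (nrow(st) == 0) stopf("'population' is empty")
  tgt <- unlist(targets[OUTCOMES])
  if (any(tgt <= 0)) stopf("calibration targets must be positive")
  rel <- rep(Inf, length(OUTCOMES))
  for (it in seq_len(max_iter)) {
    cum <- run_cohort(st, hz, NULL, years)$cumulative[OUTCOMES]
    rel <- abs(cum - tgt) / tgt
    if (max(rel) < tol / 2) {
      attr(hz, "residuals") <- stats::setNames(rel, OUTCOMES)
      attr(hz, "iterations") <- it
      return(hz)
    }
    m <- hz$multipliers
    m$diabetes <- m$diabetes * tgt[["incident_diabetes"]] / cum[["incident_diabetes"]]
    m$chd <- m$chd * tgt[["incident_chd"]] / cum[["incident_chd"]]
    m$mi <- m$mi * tgt[["total_mi"]] / cum[["total_mi"]]
    m$chd_mortality <- m$chd_mortality * tgt[["chd_deaths"]] / cum[["chd_deaths"]]
    other_target <- tgt[["all_deaths"]] - tgt[["chd_deaths"]]
    other_current <- cum[["all_deaths"]] - cum[["chd_deaths"]]
    if (other_target <= 0 || other_current <= 0)
      stopf("all-cause death target must exceed the CHD death target")
    m$other_mortality <- m$other_mortality * other_target / other_current
    hz$multipliers <- m
  }
  stopf("calibration did not converge after %d sweeps; residuals: %s",
        max_iter,
        paste(sprintf("%s=%.3f", OUTCOMES, rel), collapse = ", "))
}
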