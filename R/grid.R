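#' Specification of a scenario/sensitivity grid
#'
#' @param reductions SSB consumption reduction fractions (default 10/20/50%).
#' @param bmi_scenarios BMI-pathway scenarios to cross
#'   (`"strong"`, `"moderate"`, `"none"`).
#' @param bounds Effect-size bounds to cross (`"min"`, `"main"`, `"max"`).
#' @param subgroups Population subgroups to run.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(reductions = c(0.1, 0.2, 0.5),
                      bmi_scenarios = "moderate",
                      bounds = "main",
                      subgroups = "all") {
  if (length(reductions) == 0 || any(reductions < 0 | reductions > 1))
    stopf("'reductions' must be a non-empty set of proportions in [0, 1]")
  bad <- setdiff(bmi_scenarios, c("strong", "moderate", "none"))
  if (length(bmi_scenarios) == 0 || length(bad) > 0)
    stopf("unknown BMI scenario(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(bounds, c("min", "main", "max"))
  if (length(bounds) == 0 || length(bad) > 0)
    stopf("unknown bound(s): %s", paste(bad, collapse = ", "))
  if (length(subgroups) == 0) stopf("'subgroups' must be non-empty")
  structure(list(reductions = reductions, bmi_scenarios = bmi_scenarios,
                 bounds = bounds, subgroups = subgroups),
            class = "grid_spec")
}

#' Run the full grid of scenario analyses
#'
#' For each subgroup: generates (or reuses) the population, calibrates the
#' baseline hazards to the subgroup's scaled anticipated counts (the
#' diabetes target is scaled by the subgroup-to-statewide prevalence ratio),
#' then runs every reduction x BMI-scenario x bound combination, collecting
#' outcome differences, event-rate drops per million person-years and the
#' discounted cost report. A failing grid point is recorded in the `error`
#' column and the remaining points still run. Deterministic given the
#' population configs' seeds.
#'
#' @param population_configs Named list of [population_config()]s, one per
#'   subgroup in the grid (names must cover `grid$subgroups`).
#' @param grid A [grid_spec()].
#' @param hz An (uncalibrated) [hazard_model()].
#' @param params An [effect_parameters()] object.
#' @param cost_params A [cost_parameters()] object.
#' @param reference_population,reference_prevalence Statewide scale and
#'   diabetes prevalence the default calibration targets refer to.
#' @param years Simulation horizon.
#' @return A tibble with one row per grid point: identifiers, headline
#'   numbers (`averted_<outcome>`, `pct_<outcome>`, diabetes rate drop),
#'   and list-columns `result` ([run_scenario()] output), `rates`, `costs`;
#'   `error` holds a message for failed points, `NA` otherwise.
#' @export
run_grid <- function(population_configs, grid, hz = default_hazard_model(),
                     params = default_effect_parameters(),
                     cost_params = cost_parameters(),
                     reference_population = 16e6,
                     reference_prevalence = 0.078,
                     years = 10) {
  if (!inherits(grid, "grid_spec")) stopf("'grid' must be a grid_spec")
  missing_sg <- setdiff(grid$subgroups, names(population_configs))
  if (length(missing_sg) > 0)
    stopf("no population config for subgroup(s): %s",
          paste(missing_sg, collapse = ", "))
  rows <- list()
  for (sg in grid$subgroups) {
    cfg <- population_configs[[sg]]
    pop <- generate_population(cfg)
    st <- as_strata(pop)
    n_persons <- sum(pop$count)
    targets <- calibration_targets(
      n_persons, reference_population = reference_population,
      diabetes_scale = cfg$diabetes_prevalence / reference_prevalence)
    hz_cal <- calibrate_baseline(st, hz, targets, years = years)
    for (red in grid$reductions) {
      for (bmi in grid$bmi_scenarios) {
        for (bnd in grid$bounds) {
          row <- tibble::tibble(subgroup = sg, reduction = red,
                                bmi_scenario = bmi, bound = bnd,
                                error = NA_character_)
          res <- tryCatch({
            sc <- scenario_spec(red, bmi, bnd)
            result <- run_scenario(st, sc, hz_cal, params, years = years)
            rates <- rate_difference_per_million_py(result)
            costs <- savings_report(result, cost_params)
            list(result = result, rates = rates, costs = costs)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            row$error <- conditionMessage(res)
            row$result <- list(NULL); row$rates <- list(NULL)
            row$costs <- list(NULL)
            row$averted_diabetes <- NA_real_
          } else {
            row$result <- list(res$result)
            row$rates <- list(res$rates)
            row$costs <- list(res$costs)
            for (oc in OUTCOMES) {
              row[[paste0("averted_", oc)]] <- -res$result$difference[[oc]]
              row[[paste0("pct_", oc)]] <- res$result$percent[[oc]]
            }
            row$diabetes_rate_drop_per_million_py <-
              res$rates[["incident_diabetes"]]
          }
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

grid_point <- function(results, subgroup, reduction, bmi_scenario, bound) {
  hit <- results$subgroup == subgroup &
    abs(results$reduction - reduction) < 1e-12 &
    results$bmi_scenario == bmi_scenario & results$bound == bound
  if (!any(hit))
    stopf("grid point (%s, %.2f, %s, %s) missing from the result set",
          subgroup, reduction, bmi_scenario, bound)
  results[which(hit)[1], ]
}

#' Worst/best-case envelope around the main estimate
#'
#' Summarises the sensitivity corners for one reduction level: the minimal
#' corner combines no BMI effect with the lower effect bounds, the maximal
#' corner a strong BMI effect with the upper bounds (bounds are combined
#' simultaneously, not one at a time). For every outcome the envelope must
#' bracket the main (moderate BMI, point-estimate) case.
#'
#' @param results A [run_grid()] result containing the three corner points.
#' @param reduction Reduction level to summarise (default 0.10).
#' @param subgroup Subgroup to summarise (default `"all"`).
#' @return A tibble with one row per outcome: `anticipated`, averted counts
#'   and percent changes for the min, main and max cases, and `bracketed`.
#' @export
min_max_envelope <- function(results, reduction = 0.1, subgroup = "all") {
  pt_min <- grid_point(results, subgroup, reduction, "none", "min")
  pt_main <- grid_point(results, subgroup, reduction, "moderate", "main")
  pt_max <- grid_point(results, subgroup, reduction, "strong", "max")
  for (pt in list(pt_min, pt_main, pt_max)) {
    if (!is.na(pt$error)) stopf("corner point failed: %s", pt$error)
  }
  grab <- function(pt, what) {
    vapply(OUTCOMES, function(oc) pt[[paste0(what, "_", oc)]], numeric(1))
  }
  anticipated <- vapply(OUTCOMES, function(oc)
    pt_main$result[[1]]$anticipated[[oc]], numeric(1))
  min_averted <- grab(pt_min, "averted"); max_averted <- grab(pt_max, "averted")
  main_averted <- grab(pt_main, "averted")
  tol <- 1e-9 * pmax(1, abs(max_averted))
  tibble::tibble(outcome = OUTCOMES,
                 anticipated = anticipated,
                 min_averted = min_averted,
                 main_averted = main_averted,
                 max_averted = max_averted,
                 min_pct = -grab(pt_min, "pct"),
                 main_pct = -grab(pt_main, "pct"),
                 max_pct = -grab(pt_max, "pct"),
                 bracketed = min_averted <= main_averted + tol &
                   main_averted <= max_averted + tol)
}

#' Subgroup comparison of event-rate drops
#'
#' Table of rate differences per million person-years (with percent changes)
#' per outcome per subgroup at one grid point, the shape used to compare the
#' statewide projection with the racial/ethnic and low-income subgroups.
#'
#' @param results A [run_grid()] result covering the requested subgroups.
#' @param subgroups Subgroups (columns) to include.
#' @param reduction,bmi_scenario,bound Grid point to report.
#' @return A tibble with one row per outcome x subgroup: `outcome`,
#'   `subgroup`, `rate_drop_per_million_py`, `pct_change`.
#' @export
subgroup_table <- function(results,
                           subgroups = c("all", "african_american",
                                         "mexican_american", "low_income"),
                           reduction = 0.1, bmi_scenario = "moderate",
                           bound = "main") {
  rows <- lapply(subgroups, function(sg) {
    pt <- grid_point(results, sg, reduction, bmi_scenario, bound)
    if (!is.na(pt$error)) stopf("subgroup '%s' failed: %s", sg, pt$error)
    rates <- pt$rates[[1]]
    tibble::tibble(outcome = OUTCOMES, subgroup = sg,
                   rate_drop_per_million_py = unname(rates[OUTCOMES]),
                   pct_change = vapply(OUTCOMES, function(oc)
                     pt[[paste0("pct_", oc)]], numeric(1)))
  })
  dplyr::bind_rows(rows)
}
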