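#' Effect-size parameters for the SSB risk-factor cascade
#'
#' Bundles every effect size used to translate a change in sugar-sweetened
#' beverage (SSB) consumption into changes in energy intake, body-mass index
#' (BMI), systolic blood pressure (SBP), lipids and diabetes risk. The
#' defaults are the published meta-analytic and cohort estimates the model
#' ships with; every value can be overridden, and all downstream results are
#' conditional on them.
#'
#' The per-serving diabetes relative risk (default 1.35, 95% CI 1.14-1.59)
#' is a *total* effect; `mediated_fraction` (default 0.5) of it is assumed to
#' act through body weight and is removed on the log-RR scale by
#' [direct_diabetes_rr()] before the direct component is applied, so that the
#' BMI pathway is not double counted.
#'
#' @param serving_oz Fluid ounces per SSB serving (12 fl oz).
#' @param kcal_per_serving Energy content of one serving, kcal. The source
#'   studies do not fix this; 150 kcal is a typical regular soda. All
#'   calorie-dependent outputs are conditional on it.
#' @param compensation_fraction Fraction of removed SSB calories replaced by
#'   other foods/beverages under the moderate-BMI scenario (0.39, i.e. a 61%
#'   net energy reduction).
#' @param rr_diabetes_per_serving Total relative risk of diabetes per SSB
#'   serving per day, with `rr_diabetes_ci` its 95% CI bounds.
#' @param mediated_fraction Proportion of the diabetes RR mediated through BMI.
#' @param sbp_per_serving Reduction in SBP (mmHg) per serving-per-day
#'   reduction, by sex; `sbp_per_serving_ci` the CI bounds (lower bounds may
#'   be negative and are truncated at zero when used, see
#'   [truncate_protective()]).
#' @param sbp_per_bmi,ldl_per_bmi,hdl_per_bmi Change in SBP (mmHg), LDL and
#'   HDL cholesterol (mg/dl) per unit BMI, by sex.
#' @param rr_diabetes_per_bmi Relative risk of diabetes per unit BMI, by sex.
#' @param kcal_per_lb Energy equivalent of one pound of body weight (3500).
#' @param avg_height_m Average adult height in metres, by sex, used to map a
#'   weight change to a BMI change.
#' @param lb_to_kg Pounds-to-kilograms conversion.
#'
#' @return An object of class `effect_parameters`.
#' @seealso [apply_intervention()], [scenario_spec()], [tax_policy()]
#' @export
effect_parameters <- function(serving_oz = 12,
                              kcal_per_serving = 150,
                              compensation_fraction = 0.39,
                              rr_diabetes_per_serving = 1.35,
                              rr_diabetes_ci = c(1.14, 1.59),
                              mediated_fraction = 0.5,
                              sbp_per_serving = c(male = 0.78, female = 0.61),
                              sbp_per_serving_ci = list(male = c(0.09, 1.47),
                                                        female = c(-0.27, 1.48)),
                              sbp_per_bmi = c(male = 1.43, female = 1.24),
                              ldl_per_bmi = c(male = 2.75, female = 2.24),
                              hdl_per_bmi = c(male = -1.55, female = -0.77),
                              rr_diabetes_per_bmi = c(male = 1.26, female = 1.30),
                              kcal_per_lb = 3500,
                              avg_height_m = c(male = 1.76, female = 1.62),
                              lb_to_kg = 0.45359) {
  check_number(serving_oz, "serving_oz", lower = 1e-9)
  check_number(kcal_per_serving, "kcal_per_serving", lower = 0)
  check_proportion(compensation_fraction, "compensation_fraction")
  check_number(rr_diabetes_per_serving, "rr_diabetes_per_serving", lower = 1e-12)
  if (!is.numeric(rr_diabetes_ci) || length(rr_diabetes_ci) != 2L ||
      any(rr_diabetes_ci <= 0))
    stopf("'rr_diabetes_ci' must be two positive numbers (lower, upper)")
  check_proportion(mediated_fraction, "mediated_fraction")
  check_number(kcal_per_lb, "kcal_per_lb", lower = 1e-9)
  params <- list(
    serving_oz = serving_oz,
    kcal_per_serving = kcal_per_serving,
    compensation_fraction = compensation_fraction,
    rr_diabetes_per_serving = rr_diabetes_per_serving,
    rr_diabetes_ci = sort(rr_diabetes_ci),
    mediated_fraction = mediated_fraction,
    sbp_per_serving = check_by_sex(sbp_per_serving, "sbp_per_serving"),
    sbp_per_serving_ci = lapply(sbp_per_serving_ci[SEXES], sort),
    sbp_per_bmi = check_by_sex(sbp_per_bmi, "sbp_per_bmi"),
    ldl_per_bmi = check_by_sex(ldl_per_bmi, "ldl_per_bmi"),
    hdl_per_bmi = check_by_sex(hdl_per_bmi, "hdl_per_bmi"),
    rr_diabetes_per_bmi = check_by_sex(rr_diabetes_per_bmi, "rr_diabetes_per_bmi"),
    kcal_per_lb = kcal_per_lb,
    avg_height_m = check_by_sex(avg_height_m, "avg_height_m"),
    lb_to_kg = check_number(lb_to_kg, "lb_to_kg", lower = 1e-9)
  )
  if (any(params$rr_diabetes_per_bmi <= 0))
    stopf("'rr_diabetes_per_bmi' entries must be positive")
  structure(params, class = "effect_parameters")
}

#' @rdname effect_parameters
#' @export
default_effect_parameters <- function() effect_parameters()

#' Excise-tax policy and demand response
#'
#' Describes a volumetric excise tax on SSBs and the price elasticity of
#' demand used to translate the implied price rise into a consumption change.
#'
#' @param tax_per_oz Tax in dollars per fluid ounce (e.g. 0.01 for a
#'   penny-per-ounce excise tax).
#' @param container_oz Container size in fluid ounces.
#' @param pretax_price Pre-tax price of the container in dollars.
#' @param elasticity Price elasticity of demand (non-positive; published SSB
#'   estimates span -0.79 to -1.00).
#' @return An object of class `tax_policy`.
#' @examples
#' consumption_reduction_from_tax(tax_policy(0.01, 12, 1.00, -0.79))
#' @export
tax_policy <- function(tax_per_oz, container_oz = 12, pretax_price = 1.00,
                       elasticity = -0.79) {
  check_number(tax_per_oz, "tax_per_oz", lower = 0)
  check_number(container_oz, "container_oz", lower = 1e-9)
  check_number(pretax_price, "pretax_price")
  if (pretax_price <= 0) stopf("'pretax_price' must be positive")
  check_number(elasticity, "elasticity", upper = 0)
  structure(list(tax_per_oz = tax_per_oz, container_oz = container_oz,
                 pretax_price = pretax_price, elasticity = elasticity),
            class = "tax_policy")
}

#' Intervention scenario: reduction level, BMI pathway, effect bound
#'
#' @param reduction_fraction Fractional reduction in SSB consumption
#'   (0.10 base case; 0.20 and 0.50 as sensitivity levels).
#' @param bmi_scenario How much of the removed SSB energy translates into
#'   weight change: `"strong"` (all of it), `"moderate"` (61% net, i.e. 39%
#'   caloric compensation), or `"none"`.
#' @param bound Which end of the effect-size confidence intervals to use for
#'   the diabetes RR and the direct SBP effect: `"main"` point estimates,
#'   `"min"` lower bounds (truncated so reduced consumption is never
#'   harmful), `"max"` upper bounds.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(reduction_fraction,
                          bmi_scenario = c("moderate", "strong", "none"),
                          bound = c("main", "min", "max")) {
  check_proportion(reduction_fraction, "reduction_fraction")
  bmi_scenario <- match.arg(bmi_scenario)
  bound <- match.arg(bound)
  structure(list(reduction_fraction = reduction_fraction,
                 bmi_scenario = bmi_scenario, bound = bound),
            class = "scenario_spec")
}

#' Consumption reduction implied by an excise tax
#'
#' A volumetric tax raises the container price by
#' `tax_per_oz * container_oz / pretax_price`; the proportional consumption
#' reduction is `|elasticity|` times that price rise, capped at 1 (consumption
#' cannot fall below zero). A penny-per-ounce tax on a 12 oz, $1.00 beverage
#' with elasticity -0.79 yields a 9.5% reduction; larger or cheaper
#' containers respond more strongly (25%+ for a 32 oz container).
#'
#' @param policy A [tax_policy()].
#' @return Proportional consumption reduction in `[0, 1]`.
#' @export
consumption_reduction_from_tax <- function(policy) {
  if (!inherits(policy, "tax_policy")) stopf("'policy' must be a tax_policy")
  price_rise <- policy$tax_per_oz * policy$container_oz / policy$pretax_price
  min(1, abs(policy$elasticity) * price_rise)
}

#' Net daily energy change from an SSB consumption change
#'
#' Under the strong-BMI scenario the full energy content of the removed
#' servings is lost; under the moderate scenario 39% (by default) is
#' compensated by other foods and beverages, leaving a 61% net reduction;
#' under the no-BMI scenario energy intake is unchanged.
#'
#' @param d_servings Change in servings per day (non-positive for a
#'   reduction); vectorised.
#' @param params An [effect_parameters()] object.
#' @param bmi_scenario `"strong"`, `"moderate"` or `"none"`.
#' @return Change in kcal/day (same length as `d_servings`).
#' @export
net_calorie_change <- function(d_servings, params = default_effect_parameters(),
                               bmi_scenario = "moderate") {
  if (any(d_servings > 0)) stopf("'d_servings' must be non-positive")
  mult <- switch(bmi_scenario,
                 strong = 1,
                 moderate = 1 - params$compensation_fraction,
                 none = 0,
                 stopf("unknown BMI scenario '%s'", bmi_scenario))
  d_servings * params$kcal_per_serving * mult
}

#' Convert a sustained daily energy change into a steady-state BMI change
#'
#' Uses the 3500 kcal/lb equivalence: a sustained change of `d_kcal` per day
#' accrues `d_kcal * 365 / 3500` pounds over the first year, after which
#' weight is assumed to hold at the new steady state. The weight change is
#' converted to a BMI change via `BMI = weight(kg) / height(m)^2` at the
#' average height for each sex.
#'
#' @param d_kcal_per_day Sustained change in daily energy intake (kcal/day);
#'   vectorised.
#' @param sex `"male"` or `"female"` (recycled against `d_kcal_per_day`).
#' @param params An [effect_parameters()] object.
#' @return A list with components `d_weight_lb` and `d_bmi` (kg/m^2).
#' @export
calorie_to_bmi_delta <- function(d_kcal_per_day, sex,
                                 params = default_effect_parameters()) {
  if (!all(sex %in% SEXES)) stopf("'sex' must be 'male' or 'female'")
  height <- params$avg_height_m[sex]
  if (anyNA(height)) stopf("average height missing for some sex")
  d_weight_lb <- d_kcal_per_day * 365 / params$kcal_per_lb
  d_bmi <- d_weight_lb * params$lb_to_kg / height^2
  list(d_weight_lb = unname(d_weight_lb), d_bmi = unname(d_bmi))
}

#' Truncate an effect-size draw so SSB reduction is never harmful
#'
#' Effect sizes here are expressed in the beneficial direction (a positive
#' value means reduced consumption improves the risk factor). Confidence
#' bounds that cross zero would imply a protective effect of SSB consumption;
#' sensitivity analyses clamp such draws at zero instead.
#'
#' @param effect_value Numeric effect size(s) in the beneficial direction.
#' @return `pmax(effect_value, 0)`.
#' @export
truncate_protective <- function(effect_value) pmax(effect_value, 0)

#' Direct (non-BMI-mediated) SBP change from an SSB consumption change
#'
#' @param d_servings Change in servings/day (non-positive); vectorised.
#' @param sex `"male"`/`"female"`, recycled.
#' @param params An [effect_parameters()] object.
#' @param bound `"main"` point estimate, `"min"` truncated lower CI bound,
#'   `"max"` upper CI bound.
#' @return Change in SBP, mmHg (negative for a reduction).
#' @export
direct_sbp_delta <- function(d_servings, sex,
                             params = default_effect_parameters(),
                             bound = c("main", "min", "max")) {
  bound <- match.arg(bound)
  if (!all(sex %in% SEXES)) stopf("'sex' must be 'male' or 'female'")
  eff <- switch(bound,
                main = params$sbp_per_serving,
                min = vapply(params$sbp_per_serving_ci, function(ci)
                  truncate_protective(ci[1]), numeric(1)),
                max = vapply(params$sbp_per_serving_ci, function(ci)
                  ci[2], numeric(1)))
  unname(d_servings * eff[sex])
}

#' BMI-mediated changes in SBP, lipids and diabetes risk
#'
#' Linear per-BMI-unit effects on SBP, LDL and HDL, and a multiplicative
#' per-BMI-unit relative risk of diabetes, applied to a BMI change.
#'
#' @param d_bmi Change in BMI (kg/m^2); vectorised.
#' @param sex `"male"`/`"female"`, recycled.
#' @param params An [effect_parameters()] object.
#' @return A list with components `d_sbp` (mmHg), `d_ldl`, `d_hdl` (mg/dl)
#'   and `diabetes_rr_component` (`rr_per_bmi ^ d_bmi`, unitless).
#' @export
mediated_deltas <- function(d_bmi, sex, params = default_effect_parameters()) {
  if (any(!is.finite(d_bmi))) stopf("'d_bmi' must be finite")
  if (!all(sex %in% SEXES)) stopf("'sex' must be 'male' or 'female'")
  list(d_sbp = unname(d_bmi * params$sbp_per_bmi[sex]),
       d_ldl = unname(d_bmi * params$ldl_per_bmi[sex]),
       d_hdl = unname(d_bmi * params$hdl_per_bmi[sex]),
       diabetes_rr_component = unname(params$rr_diabetes_per_bmi[sex]^d_bmi))
}

#' Direct component of the diabetes relative risk
#'
#' Splits a total per-serving relative risk into its direct component on the
#' log-RR scale: `exp((1 - mediated_fraction) * log(rr_total))`. At 50%
#' mediation this is the square root of the total RR, which reproduces the
#' adjusted per-serving RRs of 1.07 (from a total of 1.14) and 1.26 (from
#' 1.59) used in the sensitivity bounds.
#'
#' @param rr_total Total relative risk (> 0); vectorised.
#' @param mediated_fraction Proportion mediated through BMI, in `[0, 1]`.
#' @return The direct relative risk component.
#' @export
direct_diabetes_rr <- function(rr_total, mediated_fraction = 0.5) {
  if (any(rr_total <= 0)) stopf("'rr_total' must be positive")
  check_proportion(mediated_fraction, "mediated_fraction")
  exp((1 - mediated_fraction) * log(rr_total))
}

# Per-serving diabetes RR (total scale) at a given CI bound.
rr_total_at_bound <- function(params, bound) {
  switch(bound,
         main = params$rr_diabetes_per_serving,
         min = params$rr_diabetes_ci[1],
         max = params$rr_diabetes_ci[2],
         stopf("unknown bound '%s'", bound))
}

#' Apply the full intervention cascade to population cells
#'
#' For each cell, computes the change in daily servings implied by the
#' scenario's reduction fraction, then composes the cascade: net energy
#' change, steady-state weight/BMI change, direct and BMI-mediated SBP
#' changes, BMI-mediated lipid changes, and the diabetes hazard ratio
#' `direct_rr^d_servings * rr_per_bmi^d_bmi` (both exponents are
#' non-positive for a reduction, so the hazard ratio lies in (0, 1]).
#'
#' @param cells A data frame with at least `sex` and `ssb_servings` columns
#'   (a population from [generate_population()] or its strata view).
#' @param scenario A [scenario_spec()].
#' @param params An [effect_parameters()] object.
#' @return A tibble, one row per input row, with columns `d_servings`,
#'   `d_kcal`, `d_weight_lb`, `d_bmi`, `d_sbp_direct`, `d_sbp_mediated`,
#'   `d_sbp`, `d_ldl`, `d_hdl`, `diabetes_hazard_ratio`.
#' @export
apply_intervention <- function(cells, scenario,
                               params = default_effect_parameters()) {
  if (!inherits(scenario, "scenario_spec")) stopf("'scenario' must be a scenario_spec")
  sex <- as.character(cells$sex)
  d_serv <- -scenario$reduction_fraction * cells$ssb_servings
  d_kcal <- net_calorie_change(d_serv, params, scenario$bmi_scenario)
  bmi <- calorie_to_bmi_delta(d_kcal, sex, params)
  d_sbp_direct <- direct_sbp_delta(d_serv, sex, params, scenario$bound)
  med <- mediated_deltas(bmi$d_bmi, sex, params)
  rr_direct <- direct_diabetes_rr(rr_total_at_bound(params, scenario$bound),
                                  params$mediated_fraction)
  hr <- rr_direct^d_serv * med$diabetes_rr_component
  tibble::tibble(
    d_servings = d_serv,
    d_kcal = d_kcal,
    d_weight_lb = bmi$d_weight_lb,
    d_bmi = bmi$d_bmi,
    d_sbp_direct = d_sbp_direct,
    d_sbp_mediated = med$d_sbp,
    d_sbp = d_sbp_direct + med$d_sbp,
    d_ldl = med$d_ldl,
    d_hdl = med$d_hdl,
    diabetes_hazard_ratio = hr
  )
}
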