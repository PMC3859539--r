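#' Baseline hazard model for the disease simulation
#'
#' Framingham-style default hazards for the annual-cycle state-transition
#' simulation: a log-linear diabetes incidence hazard in age and sex; a
#' log-linear CHD incidence hazard in age, sex, SBP, LDL, HDL, diabetes and
#' smoking; an MI fraction among incident CHD plus a recurrent-MI hazard in
#' the CHD-history pool; age-graded MI case fatality plus a chronic CHD
#' mortality hazard; and Gompertz non-CVD mortality with a diabetes
#' multiplier. Absolute levels are deliberately treated as *calibration
#' targets*, not claims: [calibrate_baseline()] rescales the per-outcome
#' `multipliers` so simulated baseline counts match externally supplied
#' anticipated case counts, and percent changes are the scientific surface.
#'
#' Hazards are converted to annual transition probabilities as
#' `1 - exp(-hazard)`, which lies in `[0, 1)` for any non-negative hazard.
#'
#' @param diabetes_rate50 Diabetes incidence hazard per year at age 50 (men).
#' @param diabetes_age_slope Log-linear age slope of diabetes incidence.
#' @param diabetes_sex_mult Per-sex multipliers on diabetes incidence.
#' @param chd_log_rate50 Log CHD incidence hazard at the reference profile
#'   (age 55 male ref, SBP 120, LDL 130, HDL 50, no diabetes, non-smoker).
#' @param chd_age_slope,chd_male_log_hr Log-linear age and sex terms.
#' @param chd_sbp_per_mmhg,chd_ldl_per_mgdl,chd_hdl_per_mgdl Log-hazard per
#'   unit of each risk factor.
#' @param chd_diabetes_log_hr,chd_smoking_log_hr Log hazard ratios for
#'   diabetes and current smoking.
#' @param sbp_ref,ldl_ref,hdl_ref,age_ref Reference values.
#' @param mi_fraction Fraction of incident CHD events that are MIs.
#' @param recurrent_mi_hazard Annual recurrent-MI hazard among CHD survivors.
#' @param case_fatality_60 MI case fatality at age 60; rises with
#'   `case_fatality_age_slope` per year (capped at 0.95).
#' @param chd_chronic_mortality Annual chronic CHD mortality hazard.
#' @param mortality_rate35 Non-CVD mortality hazard at age 35.
#' @param mortality_age_slope Gompertz slope of non-CVD mortality.
#' @param mortality_sex_mult Per-sex multipliers on non-CVD mortality.
#' @param diabetes_mortality_mult Non-CVD mortality multiplier for diabetes.
#' @param multipliers Per-outcome calibration multipliers (`diabetes`, `chd`,
#'   `mi`, `chd_mortality`, `other_mortality`), all 1 before calibration.
#' @return An object of class `hazard_model`.
#' @export
hazard_model <- function(diabetes_rate50 = 0.0042,
                         diabetes_age_slope = 0.03,
                         diabetes_sex_mult = c(male = 1, female = 0.85),
                         chd_log_rate50 = log(0.0045),
                         chd_age_slope = 0.075,
                         chd_male_log_hr = 0.45,
                         chd_sbp_per_mmhg = 0.016,
                         chd_ldl_per_mgdl = 0.0045,
                         chd_hdl_per_mgdl = -0.011,
                         chd_diabetes_log_hr = log(1.8),
                         chd_smoking_log_hr = log(1.7),
                         sbp_ref = 120, ldl_ref = 130, hdl_ref = 50,
                         age_ref = 55,
                         mi_fraction = 0.42,
                         recurrent_mi_hazard = 0.025,
                         case_fatality_60 = 0.22,
                         case_fatality_age_slope = 0.035,
                         chd_chronic_mortality = 0.02,
                         mortality_rate35 = 4e-4,
                         mortality_age_slope = 0.088,
                         mortality_sex_mult = c(male = 1.25, female = 0.8),
                         diabetes_mortality_mult = 1.8,
                         multipliers = list(diabetes = 1, chd = 1, mi = 1,
                                            chd_mortality = 1,
                                            other_mortality = 1)) {
  check_number(diabetes_rate50, "diabetes_rate50", lower = 0)
  check_number(mi_fraction, "mi_fraction", lower = 0, upper = 1)
  check_number(recurrent_mi_hazard, "recurrent_mi_hazard", lower = 0)
  check_number(case_fatality_60, "case_fatality_60", lower = 0, upper = 1)
  check_number(chd_chronic_mortality, "chd_chronic_mortality", lower = 0)
  check_number(mortality_rate35, "mortality_rate35", lower = 0)
  check_number(diabetes_mortality_mult, "diabetes_mortality_mult", lower = 0)
  need <- c("diabetes", "chd", "mi", "chd_mortality", "other_mortality")
  if (!is.list(multipliers) || !all(need %in% names(multipliers)))
    stopf("'multipliers' must be a list with entries %s",
          paste(need, collapse = ", "))
  if (any(unlist(multipliers[need]) < 0))
    stopf("calibration multipliers must be non-negative")
  structure(list(
    diabetes_rate50 = diabetes_rate50,
    diabetes_age_slope = diabetes_age_slope,
    diabetes_sex_mult = check_by_sex(diabetes_sex_mult, "diabetes_sex_mult"),
    chd_log_rate50 = chd_log_rate50, chd_age_slope = chd_age_slope,
    chd_male_log_hr = chd_male_log_hr,
    chd_sbp_per_mmhg = chd_sbp_per_mmhg,
    chd_ldl_per_mgdl = chd_ldl_per_mgdl,
    chd_hdl_per_mgdl = chd_hdl_per_mgdl,
    chd_diabetes_log_hr = chd_diabetes_log_hr,
    chd_smoking_log_hr = chd_smoking_log_hr,
    sbp_ref = sbp_ref, ldl_ref = ldl_ref, hdl_ref = hdl_ref,
    age_ref = age_ref,
    mi_fraction = mi_fraction, recurrent_mi_hazard = recurrent_mi_hazard,
    case_fatality_60 = case_fatality_60,
    case_fatality_age_slope = case_fatality_age_slope,
    chd_chronic_mortality = chd_chronic_mortality,
    mortality_rate35 = mortality_rate35,
    mortality_age_slope = mortality_age_slope,
    mortality_sex_mult = check_by_sex(mortality_sex_mult, "mortality_sex_mult"),
    diabetes_mortality_mult = diabetes_mortality_mult,
    multipliers = multipliers[need]
  ), class = "hazard_model")
}

#' @rdname hazard_model
#' @export
default_hazard_model <- function() hazard_model()

# --- hazard evaluation (vectorised over strata rows) ----------------------

diabetes_hazard_at <- function(hz, age, sex) {
  hz$diabetes_rate50 * exp(hz$diabetes_age_slope * (age - 50)) *
    hz$diabetes_sex_mult[sex]
}

chd_hazard_at <- function(hz, age, sex, sbp, ldl, hdl, smoking) {
  lp <- hz$chd_log_rate50 +
    hz$chd_age_slope * (age - hz$age_ref) +
    hz$chd_male_log_hr * (sex == "male") +
    hz$chd_sbp_per_mmhg * (sbp - hz$sbp_ref) +
    hz$chd_ldl_per_mgdl * (ldl - hz$ldl_ref) +
    hz$chd_hdl_per_mgdl * (hdl - hz$hdl_ref) +
    hz$chd_smoking_log_hr * smoking
  exp(lp)
}

case_fatality_at <- function(hz, age, mult = 1) {
  pmin(hz$case_fatality_60 * exp(hz$case_fatality_age_slope * (age - 60)) * mult,
       0.95)
}

other_mortality_at <- function(hz, age, sex) {
  hz$mortality_rate35 * exp(hz$mortality_age_slope * (age - 35)) *
    hz$mortality_sex_mult[sex]
}
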