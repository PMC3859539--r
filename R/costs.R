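#' Direct-medical-cost parameters
#'
#' Annual direct-care unit costs by decade-of-age band, a medical-care CPI
#' series for conversion to base-year (2012) dollars, and discounting
#' settings. The unit-cost defaults are documented placeholders of plausible
#' magnitude (the underlying state cost surveys are not published with the
#' model); cost results should be read through their orderings and
#' linearity in the unit costs, not their absolute levels.
#'
#' `diabetes_cost_by_age` covers non-CHD diabetes care; `chd_cost_by_age`
#' covers CHD care including diabetes care with co-morbid CHD.
#'
#' @param diabetes_cost_by_age,chd_cost_by_age Annual $/person-year for the
#'   age bands 35-44, 45-54, 55-64, 65-74, 75-84, 85+ (in
#'   `cost_dollar_year` dollars).
#' @param cost_dollar_year Dollar year the unit costs are expressed in.
#' @param cpi_series Named medical-care CPI index levels by year
#'   (approximate published levels; only ratios matter).
#' @param base_dollar_year Dollar year results are reported in (2012).
#' @param discount_rate Annual discount rate (0.03).
#' @param discount_base_year Year to which costs are discounted (2013, the
#'   first simulated year).
#' @param chd_years_per_event Mean years of CHD care attributed to one
#'   diabetes-related CHD event (used by the `diabetes_related_chd`
#'   category).
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(diabetes_cost_by_age = c(4300, 5200, 6100, 7400, 8300, 8900),
                            chd_cost_by_age = c(9800, 10900, 12000, 13500, 14200, 14600),
                            cost_dollar_year = 2010,
                            cpi_series = c("2005" = 323.2, "2006" = 336.2,
                                           "2007" = 351.1, "2008" = 364.1,
                                           "2009" = 375.6, "2010" = 388.4,
                                           "2011" = 400.3, "2012" = 414.9,
                                           "2013" = 425.1),
                            base_dollar_year = 2012,
                            discount_rate = 0.03,
                            discount_base_year = 2013,
                            chd_years_per_event = 5) {
  nb <- length(AGE_BAND_BREAKS)
  for (nm in c("diabetes_cost_by_age", "chd_cost_by_age")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != nb || any(v < 0))
      stopf("'%s' must be %d non-negative annual costs (age bands %s+)",
            nm, nb, paste(AGE_BAND_BREAKS, collapse = ", "))
  }
  if (is.null(names(cpi_series)) || any(cpi_series <= 0))
    stopf("'cpi_series' must be positive index values named by year")
  check_number(discount_rate, "discount_rate", lower = 0)
  check_number(chd_years_per_event, "chd_years_per_event", lower = 0)
  structure(list(diabetes_cost_by_age = diabetes_cost_by_age,
                 chd_cost_by_age = chd_cost_by_age,
                 cost_dollar_year = cost_dollar_year,
                 cpi_series = cpi_series,
                 base_dollar_year = base_dollar_year,
                 discount_rate = discount_rate,
                 discount_base_year = discount_base_year,
                 chd_years_per_event = chd_years_per_event),
            class = "cost_parameters")
}

#' Convert an amount between dollar years via the medical-care CPI
#'
#' @param amount Dollar amount(s) in `from_year` dollars.
#' @param from_year Year the amount is expressed in.
#' @param params A [cost_parameters()] object.
#' @param to_year Target dollar year (default the params' base year, 2012).
#' @return `amount * cpi(to_year) / cpi(from_year)`.
#' @export
cpi_adjust <- function(amount, from_year, params = cost_parameters(),
                       to_year = params$base_dollar_year) {
  cpi <- params$cpi_series
  for (y in c(from_year, to_year)) {
    if (!as.character(y) %in% names(cpi))
      stopf("year %s is not in the CPI series", y)
  }
  amount * cpi[[as.character(to_year)]] / cpi[[as.character(from_year)]]
}

#' Present value of a stream of annual amounts
#'
#' Discounts each amount to the base year at the configured annual rate:
#' `sum(amount_t / (1 + r)^(t - base_year))`.
#'
#' @param amounts_by_year Numeric vector named by calendar year.
#' @param params A [cost_parameters()] object.
#' @return The present value (a single number).
#' @export
discount_stream <- function(amounts_by_year, params = cost_parameters()) {
  yrs <- as.numeric(names(amounts_by_year))
  if (anyNA(yrs)) stopf("'amounts_by_year' must be named by calendar year")
  if (any(yrs < params$discount_base_year))
    stopf("years before the discount base year (%d) are not supported",
          params$discount_base_year)
  sum(amounts_by_year / (1 + params$discount_rate)^(yrs - params$discount_base_year))
}

#' Discounted medical-cost savings of an intervention
#'
#' Converts the paired baseline/intervention person-state-year tallies of a
#' [run_scenario()] result into discounted 2012-dollar savings in three
#' categories: `diabetes_direct` (non-CHD diabetes care person-years valued
#' at the diabetes unit costs), `total_chd` (CHD-state person-years at the
#' CHD unit costs), and `diabetes_related_chd` (averted diabetes-attributable
#' CHD events, each costed over `chd_years_per_event` years of CHD care).
#' Savings are baseline minus intervention, so positive values are money
#' saved.
#'
#' @param result A `scenario_result`.
#' @param params A [cost_parameters()] object.
#' @return A tibble of class `cost_report` with columns `category`,
#'   `savings_usd`, `savings_millions` and `pct_of_baseline` (savings as a
#'   percent of the baseline arm's discounted category cost).
#' @export
savings_report <- function(result, params = cost_parameters()) {
  if (!inherits(result, "scenario_result"))
    stopf("'result' must be a scenario_result")
  b <- result$baseline; i <- result$intervention
  if (min(b$py_dm_band, i$py_dm_band, b$py_chd_band, i$py_chd_band) < 0)
    stopf("negative person-state-years in the tallies")
  cost_dm <- cpi_adjust(params$diabetes_cost_by_age, params$cost_dollar_year,
                        params)
  cost_chd <- cpi_adjust(params$chd_cost_by_age, params$cost_dollar_year,
                         params)
  years <- as.numeric(rownames(b$py_dm_band))
  stream <- function(py_band, costs) {
    stats::setNames(as.numeric(py_band %*% costs), years)
  }
  base_dm <- stream(b$py_dm_band, cost_dm)
  int_dm <- stream(i$py_dm_band, cost_dm)
  base_chd <- stream(b$py_chd_band, cost_chd)
  int_chd <- stream(i$py_chd_band, cost_chd)
  sav_dm <- discount_stream(base_dm - int_dm, params)
  sav_chd <- discount_stream(base_chd - int_chd, params)
  pv_base_dm <- discount_stream(base_dm, params)
  pv_base_chd <- discount_stream(base_chd, params)

  # diabetes-related CHD: averted diabetes-attributable CHD events, each
  # costed over chd_years_per_event years of CHD care from the event year
  averted_events <- b$per_year$dm_attrib_chd - i$per_year$dm_attrib_chd
  w_chd <- colSums(b$py_chd_band)
  mean_chd_cost <- if (sum(w_chd) > 0) {
    sum(cost_chd * w_chd) / sum(w_chd)
  } else mean(cost_chd)
  r <- params$discount_rate
  dur <- max(0, round(params$chd_years_per_event))
  pv_per_event <- vapply(years, function(y) {
    if (dur == 0) return(0)
    sum(mean_chd_cost / (1 + r)^(y - params$discount_base_year + seq_len(dur) - 1))
  }, numeric(1))
  sav_dm_chd <- sum(averted_events * pv_per_event)
  pv_base_dm_chd <- sum(b$per_year$dm_attrib_chd * pv_per_event)

  out <- tibble::tibble(
    category = c("diabetes_direct", "diabetes_related_chd", "total_chd"),
    savings_usd = c(sav_dm, sav_dm_chd, sav_chd),
    savings_millions = round(c(sav_dm, sav_dm_chd, sav_chd) / 1e6, 1),
    pct_of_baseline = 100 * c(
      if (pv_base_dm > 0) sav_dm / pv_base_dm else 0,
      if (pv_base_dm_chd > 0) sav_dm_chd / pv_base_dm_chd else 0,
      if (pv_base_chd > 0) sav_chd / pv_base_chd else 0))
  structure(out, class = c("cost_report", class(out)))
}
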