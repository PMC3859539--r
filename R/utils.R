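# Internal helpers shared across modules.

SEXES <- c("male", "female")
ALIVE_STATES <- c("well", "diabetes", "chd", "diabetes_and_chd")
ALL_STATES <- c(ALIVE_STATES, "dead_chd", "dead_other")
OUTCOMES <- c("incident_diabetes", "incident_chd", "total_mi",
              "chd_deaths", "all_deaths")

# Cost accounting uses decade-of-age bands; ages above the last break share
# the final band.
AGE_BAND_BREAKS <- c(35, 45, 55, 65, 75, 85)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stopf("'%s' must lie in [%s, %s] (got %s)",
          name, format(lower), format(upper), format(x))
  invisible(as.numeric(x))
}

check_proportion <- function(x, name) check_number(x, name, 0, 1)

# A per-sex numeric pair, returned in canonical (male, female) order.
check_by_sex <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) ||
      is.null(names(x)) || !setequal(names(x), SEXES))
    stopf("'%s' must be a numeric vector with names 'male' and 'female'", name)
  x[SEXES]
}

age_band <- function(age) findInterval(age, AGE_BAND_BREAKS)

# Percent change of a difference relative to a baseline count, at the
# rounding the report tables use.
percent_change <- function(difference, baseline, digits = 1) {
  if (any(baseline <= 0)) stopf("'baseline' must be positive")
  round(100 * difference / baseline, digits)
}
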