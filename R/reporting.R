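# Shared readers/writers, run manifests and presentation formatting.
# Full-precision values are never mutated by presentation rounding: the
# format_* helpers return character renderings and leave their inputs alone.

#' Write a result table as CSV with a checked schema
#'
#' Writes with a stable column order and locale-independent number
#' formatting. Presentation rounding is *not* applied here; use the
#' `format_*` helpers to render a report-style view.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @param schema Optional character vector of required column names (order
#'   enforced); a mismatch is an error.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema = NULL) {
  if (!is.data.frame(records)) stopf("'records' must be a data frame")
  if (!is.null(schema)) {
    if (!setequal(names(records), schema))
      stopf("schema mismatch: expected columns {%s}, got {%s}",
            paste(schema, collapse = ", "),
            paste(names(records), collapse = ", "))
    records <- records[, schema, drop = FALSE]
  }
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param ... Passed to [utils::read.csv()].
#' @export
read_table <- function(path, ...) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE, ...))
}

#' Report-style rendering of counts and percent changes
#'
#' `format_count()` rounds to the nearest `nearest` persons (report tables
#' print counts to the nearest 100 or 1,000) and adds thousands separators.
#' `format_count_percent()` renders `"-6,000 (-0.5%)"`-style cells from a
#' difference and its baseline anticipated count.
#'
#' @param x Count(s).
#' @param nearest Rounding granularity in persons.
#' @return Character vector.
#' @export
format_count <- function(x, nearest = 100) {
  v <- round(x / nearest) * nearest
  formatC(v, format = "d", big.mark = ",")
}

#' @rdname format_count
#' @param difference Signed difference in counts (negative = averted).
#' @param baseline Baseline anticipated count.
#' @param digits Decimal places for the percent.
#' @export
format_count_percent <- function(difference, baseline, nearest = 100,
                                 digits = 1) {
  pct <- percent_change(difference, baseline, digits)
  sprintf("%s (%s%%)", format_count(difference, nearest),
          formatC(pct, format = "f", digits = digits))
}

# Strict constructor call: every supplied key must be a formal argument.
call_strict <- function(fn, args, section) {
  known <- names(formals(fn))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0)
    stopf("unknown key(s) in config section '%s': %s",
          section, paste(unknown, collapse = ", "))
  numeric_formals <- setdiff(known, c("subgroup", "bmi_scenarios", "bounds",
                                      "subgroups"))
  for (k in intersect(names(args), numeric_formals)) {
    if (is.character(args[[k]]) && is.na(suppressWarnings(as.numeric(args[[k]])[1])) &&
        !k %in% c("subgroup"))
      stopf("malformed numeric value for key '%s' in section '%s'", k, section)
  }
  do.call(fn, args)
}

yaml_by_sex <- function(x) {
  if (is.list(x) && all(SEXES %in% names(x))) {
    v <- unlist(x[SEXES])
    if (all(vapply(x[SEXES], length, integer(1)) == 1)) {
      return(stats::setNames(as.numeric(v), SEXES))
    }
    return(lapply(x[SEXES], as.numeric))
  }
  x
}

#' Load a validated configuration bundle from YAML
#'
#' Reads a YAML file with optional sections `population`, `effects`, `tax`,
#' `costs` and `grid`; each section overrides the corresponding constructor
#' defaults (so an absent section yields the full default bundle, including
#' every shipped effect size). Unknown sections or keys are rejected with a
#' message naming them; malformed numerics are rejected naming the key.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A list with elements `population` ([population_config()]),
#'   `effects` ([effect_parameters()]), `tax` ([tax_policy()] or `NULL` when
#'   the section is absent), `costs` ([cost_parameters()]) and `grid`
#'   ([grid_spec()]).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("population", "effects", "tax", "costs", "grid")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  eff <- raw$effects %||% list()
  for (k in c("sbp_per_serving", "sbp_per_bmi", "ldl_per_bmi", "hdl_per_bmi",
              "rr_diabetes_per_bmi", "avg_height_m", "sbp_per_serving_ci")) {
    if (!is.null(eff[[k]])) eff[[k]] <- yaml_by_sex(eff[[k]])
  }
  popr <- raw$population %||% list()
  for (k in c("sex_fractions")) {
    if (!is.null(popr[[k]])) popr[[k]] <- yaml_by_sex(popr[[k]])
  }
  for (k in c("bmi_mean_sd", "sbp_mean_sd", "ldl_mean_sd", "hdl_mean_sd")) {
    if (!is.null(popr[[k]])) popr[[k]] <- lapply(popr[[k]], as.numeric)
  }
  costs <- raw$costs %||% list()
  if (!is.null(costs$cpi_series)) costs$cpi_series <- unlist(costs$cpi_series)
  list(
    population = call_strict(population_config, popr, "population"),
    effects = call_strict(effect_parameters, eff, "effects"),
    tax = if (is.null(raw$tax)) NULL else call_strict(tax_policy, raw$tax, "tax"),
    costs = call_strict(cost_parameters, costs, "costs"),
    grid = call_strict(grid_spec, raw$grid %||% list(), "grid")
  )
}

#' Run manifest recording how a set of tables was produced
#'
#' @param config A list of configuration objects (as from [load_config()]).
#' @param seeds Named or unnamed integer seeds used.
#' @param calibration_residuals Optional named residual vector from
#'   [calibrate_baseline()].
#' @param path Optional JSON path to write the manifest to.
#' @return The manifest list (invisibly when written to `path`).
#' @export
run_manifest <- function(config, seeds, calibration_residuals = NULL,
                         path = NULL) {
  manifest <- list(
    config_hash = rlang::hash(config),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("ssbimpact")),
    calibration_residuals = as.list(calibration_residuals),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
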