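#' Target marginals for a synthetic adult population
#'
#' Declares the marginal structure a synthetic population should match:
#' demographic composition, subgroup-specific SSB consumption, diabetes and
#' CHD prevalence, and risk-factor distributions. Defaults for `ssb_mean`,
#' `diabetes_prevalence` and `bmi_mean_sd` are resolved from the subgroup
#' profile (see [subgroup_profile()]) when not given explicitly.
#'
#' SSB servings/day are modelled as a zero-inflated gamma: a point mass of
#' non-consumers (`ssb_zero_fraction`) plus a gamma distribution with shape
#' `ssb_shape` among consumers, scaled so the overall mean equals `ssb_mean`.
#' Surveys report daily frequency with many non-consumers; the published
#' subgroup summaries give only means, so the zero fraction and shape are
#' modelling choices.
#'
#' Diabetes and CHD prevalence rise log-linearly with age
#' (`prevalence_age_slope` per year), normalised so the population-weighted
#' prevalence matches the scalar target.
#'
#' @param total_count Number of persons to generate.
#' @param age_range Closed integer age interval, default 35-94 (the modelled
#'   outcome relationships are adult-onset).
#' @param sex_fractions Named proportions summing to 1.
#' @param subgroup One of `"all"`, `"white"`, `"african_american"`,
#'   `"mexican_american"`, `"low_income"`.
#' @param ssb_mean Mean SSB servings/day (subgroup default if `NULL`).
#' @param ssb_zero_fraction Proportion of non-consumers.
#' @param ssb_shape Gamma shape (dispersion) among consumers.
#' @param diabetes_prevalence,chd_prevalence Overall prevalences in `[0, 1]`.
#' @param bmi_mean_sd,sbp_mean_sd,ldl_mean_sd,hdl_mean_sd Per-sex lists of
#'   `c(mean, sd)` for BMI (kg/m^2), SBP (mmHg), LDL and HDL (mg/dl).
#' @param smoking_prevalence Proportion of current smokers.
#' @param n_ssb_bins Number of consumption bins (deciles of the positive
#'   draws, plus a zero bin) used for cell aggregation.
#' @param seed Integer RNG seed; identical config + seed gives a
#'   bit-identical population.
#' @param age_decay Exponential decay rate of the age pyramid per year.
#' @param prevalence_age_slope Log-linear age slope shared by the diabetes
#'   and CHD prevalence curves.
#' @param bounds Physiologic truncation bounds for the risk-factor draws.
#' @return An object of class `population_config`.
#' @export
population_config <- function(total_count = 1e5,
                              age_range = c(35L, 94L),
                              sex_fractions = c(male = 0.49, female = 0.51),
                              subgroup = c("all", "white", "african_american",
                                           "mexican_american", "low_income"),
                              ssb_mean = NULL,
                              ssb_zero_fraction = 0.30,
                              ssb_shape = 1.2,
                              diabetes_prevalence = NULL,
                              chd_prevalence = 0.055,
                              bmi_mean_sd = NULL,
                              sbp_mean_sd = list(male = c(127, 15), female = c(124, 16)),
                              ldl_mean_sd = list(male = c(128, 33), female = c(125, 34)),
                              hdl_mean_sd = list(male = c(45, 12), female = c(55, 14)),
                              smoking_prevalence = 0.12,
                              n_ssb_bins = 10,
                              seed = 1L,
                              age_decay = 0.025,
                              prevalence_age_slope = 0.05,
                              bounds = list(bmi = c(12, 70), sbp = c(80, 230),
                                            ldl = c(30, 300), hdl = c(10, 120))) {
  subgroup <- match.arg(subgroup)
  profile <- subgroup_profile(subgroup)
  ssb_mean <- ssb_mean %||% profile$ssb_mean
  diabetes_prevalence <- diabetes_prevalence %||% profile$diabetes_prevalence
  bmi_mean_sd <- bmi_mean_sd %||% profile$bmi_mean_sd

  check_number(total_count, "total_count", lower = 0)
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    stopf("'age_range' must be a non-empty closed interval c(lo, hi)")
  sex_fractions <- check_by_sex(sex_fractions, "sex_fractions")
  if (any(sex_fractions < 0) || abs(sum(sex_fractions) - 1) > 1e-8)
    stopf("'sex_fractions' must be non-negative and sum to 1")
  check_number(ssb_mean, "ssb_mean", lower = 0)
  check_proportion(ssb_zero_fraction, "ssb_zero_fraction")
  if (ssb_mean > 0 && ssb_zero_fraction >= 1)
    stopf("'ssb_zero_fraction' must be < 1 when 'ssb_mean' > 0")
  check_number(ssb_shape, "ssb_shape", lower = 1e-9)
  check_proportion(diabetes_prevalence, "diabetes_prevalence")
  check_proportion(chd_prevalence, "chd_prevalence")
  check_proportion(smoking_prevalence, "smoking_prevalence")
  check_number(n_ssb_bins, "n_ssb_bins", lower = 1)
  check_number(seed, "seed")
  for (nm in c("bmi_mean_sd", "sbp_mean_sd", "ldl_mean_sd", "hdl_mean_sd")) {
    v <- get(nm)
    if (!is.list(v) || !setequal(names(v), SEXES) ||
        !all(vapply(v, function(x) is.numeric(x) && length(x) == 2 && x[2] >= 0,
                    logical(1))))
      stopf("'%s' must be a list with per-sex c(mean, sd), sd >= 0", nm)
  }
  structure(list(total_count = as.integer(round(total_count)),
                 age_range = as.integer(age_range),
                 sex_fractions = sex_fractions, subgroup = subgroup,
                 ssb_mean = ssb_mean, ssb_zero_fraction = ssb_zero_fraction,
                 ssb_shape = ssb_shape,
                 diabetes_prevalence = diabetes_prevalence,
                 chd_prevalence = chd_prevalence,
                 bmi_mean_sd = bmi_mean_sd[SEXES], sbp_mean_sd = sbp_mean_sd[SEXES],
                 ldl_mean_sd = ldl_mean_sd[SEXES], hdl_mean_sd = hdl_mean_sd[SEXES],
                 smoking_prevalence = smoking_prevalence,
                 n_ssb_bins = as.integer(n_ssb_bins), seed = as.integer(seed),
                 age_decay = age_decay,
                 prevalence_age_slope = prevalence_age_slope,
                 bounds = bounds),
            class = "population_config")
}

#' Subgroup marginal profiles
#'
#' Survey-based per-subgroup targets: mean SSB servings/day (whites 0.47,
#' African Americans 0.51, Mexican Americans 0.59, low income 0.70) and adult
#' diabetes prevalence (whites 6.7%, Mexican Americans 9.2%, African
#' Americans 11.5%; statewide 7.8%). The all-California SSB mean (0.50) is a
#' population-weighted blend of the subgroup values, and the low-income
#' diabetes prevalence (8.0%) is interpolated from the income gradient; both
#' are documented stand-ins for unpublished survey summaries. BMI means
#' reflect the subgroups' reported obesity burden.
#'
#' @param subgroup Subgroup name.
#' @return A list with `ssb_mean`, `diabetes_prevalence`, `bmi_mean_sd`.
#' @export
subgroup_profile <- function(subgroup = c("all", "white", "african_american",
                                          "mexican_american", "low_income")) {
  subgroup <- match.arg(subgroup)
  switch(subgroup,
    all = list(ssb_mean = 0.50, diabetes_prevalence = 0.078,
               bmi_mean_sd = list(male = c(27.4, 5.0), female = c(27.0, 5.8))),
    white = list(ssb_mean = 0.47, diabetes_prevalence = 0.067,
                 bmi_mean_sd = list(male = c(26.8, 4.7), female = c(26.4, 5.4))),
    african_american = list(ssb_mean = 0.51, diabetes_prevalence = 0.115,
                            bmi_mean_sd = list(male = c(28.6, 5.5), female = c(29.6, 6.5))),
    mexican_american = list(ssb_mean = 0.59, diabetes_prevalence = 0.092,
                            bmi_mean_sd = list(male = c(28.4, 5.1), female = c(28.9, 6.0))),
    low_income = list(ssb_mean = 0.70, diabetes_prevalence = 0.080,
                      bmi_mean_sd = list(male = c(28.0, 5.3), female = c(28.3, 6.2))))
}

# Age-specific prevalence curve normalised so the population-weighted mean
# over the realised age distribution equals the scalar target.
prevalence_by_age <- function(overall, ages, age_weights, slope, cap = 0.6) {
  if (overall == 0) return(rep(0, length(ages)))
  g <- exp(slope * (ages - stats::weighted.mean(ages, age_weights)))
  p <- overall * g / stats::weighted.mean(g, age_weights)
  pmin(p, cap)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a seeded synthetic adult population
#'
#' Draws `total_count` individuals matching the config's marginals and
#' aggregates them into population cells: one row per 1-year age x sex x
#' SSB-consumption bin x health state, carrying the stratum's mean risk
#' factors and a person count. Continuous risk factors are drawn
#' independently within age/sex strata (no correlation structure is imposed);
#' diabetes and CHD prevalence follow age-normalised curves. Identical
#' `(config, seed)` yields a bit-identical population.
#'
#' @param config A [population_config()].
#' @return A tibble of class `ssb_population` with columns `age`, `sex`,
#'   `subgroup`, `ssb_bin`, `ssb_servings`, `bmi`, `sbp`, `ldl`, `hdl`,
#'   `smoking` (cell smoker fraction), `health_state`, `count`, and the
#'   config stored in `attr(, "config")`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "population_config"))
    stopf("'config' must be a population_config")
  empty <- tibble::tibble(age = integer(), sex = character(),
                          subgroup = character(), ssb_bin = integer(),
                          ssb_servings = numeric(), bmi = numeric(),
                          sbp = numeric(), ldl = numeric(), hdl = numeric(),
                          smoking = numeric(), health_state = character(),
                          count = numeric())
  if (config$total_count == 0) {
    out <- structure(empty, class = c("ssb_population", class(empty)))
    attr(out, "config") <- config
    return(out)
  }
  set.seed(config$seed)
  n <- config$total_count
  ages <- seq(config$age_range[1], config$age_range[2])
  w <- exp(-config$age_decay * (ages - ages[1]))
  age <- sample(ages, n, replace = TRUE, prob = w)
  # exact proportional allocation: the sex marginal is a design margin, not
  # a sampled one
  n_male <- round(n * config$sex_fractions[["male"]])
  sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))

  # zero-inflated gamma SSB consumption
  if (config$ssb_mean > 0) {
    is_zero <- stats::runif(n) < config$ssb_zero_fraction
    mean_pos <- config$ssb_mean / (1 - config$ssb_zero_fraction)
    ssb <- ifelse(is_zero, 0,
                  stats::rgamma(n, shape = config$ssb_shape,
                                scale = mean_pos / config$ssb_shape))
  } else {
    ssb <- rep(0, n)
  }

  draw_rf <- function(spec, lo, hi) {
    out <- numeric(n)
    for (s in SEXES) {
      idx <- sex == s
      out[idx] <- rtrunc_norm(sum(idx), spec[[s]][1], spec[[s]][2], lo, hi)
    }
    out
  }
  b <- config$bounds
  bmi <- draw_rf(config$bmi_mean_sd, b$bmi[1], b$bmi[2])
  sbp <- draw_rf(config$sbp_mean_sd, b$sbp[1], b$sbp[2])
  ldl <- draw_rf(config$ldl_mean_sd, b$ldl[1], b$ldl[2])
  hdl <- draw_rf(config$hdl_mean_sd, b$hdl[1], b$hdl[2])
  smoker <- stats::runif(n) < config$smoking_prevalence

  p_dm <- prevalence_by_age(config$diabetes_prevalence, ages, w,
                            config$prevalence_age_slope)[match(age, ages)]
  p_chd <- prevalence_by_age(config$chd_prevalence, ages, w,
                             config$prevalence_age_slope, cap = 0.5)[match(age, ages)]
  has_dm <- stats::runif(n) < p_dm
  has_chd <- stats::runif(n) < p_chd
  state <- ifelse(has_dm & has_chd, "diabetes_and_chd",
                  ifelse(has_dm, "diabetes",
                         ifelse(has_chd, "chd", "well")))

  # consumption bins: bin 0 = non-consumers, bins 1..k = quantile slices
  pos <- ssb[ssb > 0]
  if (length(pos) > 0 && config$n_ssb_bins > 1) {
    brk <- unique(stats::quantile(pos, probs = seq(0, 1, length.out = config$n_ssb_bins + 1)))
    bin <- ifelse(ssb == 0, 0L, findInterval(ssb, brk, rightmost.closed = TRUE))
  } else {
    bin <- ifelse(ssb == 0, 0L, 1L)
  }

  ind <- tibble::tibble(age = age, sex = sex, ssb_bin = as.integer(bin),
                        ssb = ssb, bmi = bmi, sbp = sbp, ldl = ldl, hdl = hdl,
                        smoker = as.numeric(smoker), health_state = state)
  # stratum-level risk-factor means shared across health states
  strata_means <- ind |>
    dplyr::group_by(.data$age, .data$sex, .data$ssb_bin) |>
    dplyr::summarise(ssb_servings = mean(.data$ssb), bmi = mean(.data$bmi),
                     sbp = mean(.data$sbp), ldl = mean(.data$ldl),
                     hdl = mean(.data$hdl), smoking = mean(.data$smoker),
                     .groups = "drop")
  counts <- ind |>
    dplyr::count(.data$age, .data$sex, .data$ssb_bin, .data$health_state,
                 name = "count")
  cells <- dplyr::left_join(counts, strata_means,
                            by = c("age", "sex", "ssb_bin")) |>
    dplyr::mutate(subgroup = config$subgroup, count = as.numeric(.data$count)) |>
    dplyr::select("age", "sex", "subgroup", "ssb_bin", "ssb_servings",
                  "bmi", "sbp", "ldl", "hdl", "smoking", "health_state",
                  "count") |>
    dplyr::arrange(.data$age, .data$sex, .data$ssb_bin, .data$health_state)
  out <- structure(cells, class = c("ssb_population", class(cells)))
  attr(out, "config") <- config
  out
}

#' Check a population's realised marginals against its targets
#'
#' @param population An `ssb_population`.
#' @param config The [population_config()] holding the targets (defaults to
#'   the one stored on the population).
#' @param tolerances List with `mean_rel` (relative tolerance for means,
#'   default 2%) and `prev_abs` (absolute tolerance for prevalences and
#'   fractions, default 0.005 i.e. 0.5 percentage points).
#' @return A tibble with one row per targeted marginal: `marginal`, `target`,
#'   `realized`, `tolerance`, `pass`.
#' @export
validate_marginals <- function(population, config = attr(population, "config"),
                               tolerances = list(mean_rel = 0.02,
                                                 prev_abs = 0.005)) {
  if (nrow(population) == 0) stopf("'population' is empty")
  if (is.null(config)) stopf("no config supplied or attached to the population")
  wmean <- function(x, w) stats::weighted.mean(x, w)
  cnt <- population$count
  rows <- list()
  add <- function(name, target, realized, tol, relative) {
    ok <- if (relative && target != 0) {
      abs(realized - target) <= tol * abs(target)
    } else if (relative) {
      abs(realized - target) <= tol  # zero target: fall back to absolute
    } else {
      abs(realized - target) <= tol
    }
    rows[[length(rows) + 1]] <<- tibble::tibble(
      marginal = name, target = target, realized = realized,
      tolerance = tol, type = if (relative) "relative" else "absolute",
      pass = ok)
  }
  add("ssb_mean", config$ssb_mean, wmean(population$ssb_servings, cnt),
      tolerances$mean_rel, TRUE)
  dm_states <- c("diabetes", "diabetes_and_chd")
  add("diabetes_prevalence", config$diabetes_prevalence,
      sum(cnt[population$health_state %in% dm_states]) / sum(cnt),
      tolerances$prev_abs, FALSE)
  add("chd_prevalence", config$chd_prevalence,
      sum(cnt[population$health_state %in% c("chd", "diabetes_and_chd")]) / sum(cnt),
      tolerances$prev_abs, FALSE)
  add("male_fraction", config$sex_fractions[["male"]],
      sum(cnt[population$sex == "male"]) / sum(cnt),
      tolerances$prev_abs, FALSE)
  add("smoking_prevalence", config$smoking_prevalence,
      wmean(population$smoking, cnt), tolerances$prev_abs, FALSE)
  for (s in SEXES) {
    idx <- population$sex == s
    for (rf in c("bmi", "sbp", "ldl", "hdl")) {
      add(paste(rf, "mean", s, sep = "_"),
          config[[paste0(rf, "_mean_sd")]][[s]][1],
          wmean(population[[rf]][idx], cnt[idx]),
          tolerances$mean_rel, TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Pivot a population to its wide strata view used by the simulator
#'
#' One row per age x sex x SSB bin stratum, with per-state person counts in
#' columns `n_well`, `n_diabetes`, `n_chd`, `n_diabetes_and_chd`,
#' `n_dead_chd`, `n_dead_other`.
#'
#' @param population An `ssb_population` (long cells).
#' @return A plain data frame (strata view).
#' @export
as_strata <- function(population) {
  if (nrow(population) == 0) stopf("'population' is empty")
  wide <- population |>
    tidyr::pivot_wider(names_from = "health_state", values_from = "count",
                       values_fill = 0, names_prefix = "n_")
  for (s in ALL_STATES) {
    col <- paste0("n_", s)
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide <- wide[, c("age", "sex", "subgroup", "ssb_bin", "ssb_servings",
                   "bmi", "sbp", "ldl", "hdl", "smoking",
                   paste0("n_", ALL_STATES))]
  as.data.frame(wide)
}

#' Write / read a population as CSV plus a JSON sidecar
#'
#' The CSV holds one row per cell with the documented header; the sidecar
#' (`<path>.json`) records the generating config, seed and package version so
#' every table traces back to its inputs.
#'
#' @param population An `ssb_population`.
#' @param path CSV path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns the population with its config re-attached when the sidecar is
#'   present.
#' @export
write_population <- function(population, path) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE)
  cfg <- attr(population, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(
      list(config = unclass(cfg), package_version = as.character(utils::packageVersion("ssbimpact"))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out <- structure(df, class = c("ssb_population", class(df)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "config") <- meta$config
  }
  out
}
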