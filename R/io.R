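# Readers, writers and report-shaped tables. All tabular IO is tidy CSV
# (UTF-8, header required); reported prevalences are rounded half-up to one
# decimal at this edge only.

#' Render a scenario-by-year prevalence table
#'
#' Rows are scenarios (input order), columns calendar years, values adult
#' prevalence rounded half-up to one decimal — the layout of the published
#' projection tables.
#'
#' @param results list of `projection_series`.
#' @param years report years (must lie inside every series' horizon).
#' @param sex `"male"`, `"female"` or `"total"`.
#' @param digits decimals (default 1).
#' @return data.frame with a `scenario` column and one column per year.
#' @export
render_scenario_table <- function(results, years = c(2022, 2025, 2030, 2035, 2040, 2045, 2050),
                                  sex = c("male", "female", "total"), digits = 1) {
  sex <- match.arg(sex)
  cols <- c(list(scenario = character(0)),
            setNames(rep(list(numeric(0)), length(years)), as.character(years)))
  if (length(results) == 0L) return(as.data.frame(cols, check.names = FALSE))
  rows <- lapply(results, function(ser) {
    idx <- match(years, ser$year)
    if (anyNA(idx)) stop_validation("report years outside a series' horizon")
    c(list(scenario = attr(ser, "scenario") %||% "<unnamed>"),
      setNames(as.list(round_half_up(ser[[sex]][idx], digits)), as.character(years)))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a projection series as tidy CSV
#'
#' Columns: `scenario`, `year`, `sex`, `prevalence_pct` (full precision).
#'
#' @param series a `projection_series` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_projection_csv <- function(series, path) {
  if (inherits(series, "projection_series")) series <- list(series)
  tidy <- do.call(rbind, lapply(series, function(ser) {
    data.frame(scenario = attr(ser, "scenario") %||% "<unnamed>",
               year = rep(ser$year, 3),
               sex = rep(c("male", "female", "total"), each = nrow(ser)),
               prevalence_pct = c(ser$male, ser$female, ser$total))
  }))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}

#' Compare a projection with an external survey series
#'
#' Purely descriptive: per-year differences (model minus survey) and their
#' maximum absolute value, for whichever (year, sex) pairs the survey
#' provides. No survey data ship with the package.
#'
#' @param series a `projection_series`.
#' @param survey data.frame (or CSV path) with columns `year`, `sex`,
#'   `prevalence_pct`.
#' @return list with `table` (year, sex, model, survey, diff) and
#'   `max_abs_diff`.
#' @export
compare_to_survey <- function(series, survey) {
  if (is.character(survey)) survey <- utils::read.csv(survey, stringsAsFactors = FALSE)
  need <- c("year", "sex", "prevalence_pct")
  if (!all(need %in% names(survey))) {
    stop_validation("survey must have columns ", paste(need, collapse = ", "))
  }
  if (!all(survey$sex %in% c("male", "female", "total"))) {
    stop_validation("survey sex must be male/female/total")
  }
  model <- mapply(function(y, s) {
    i <- match(y, series$year)
    if (is.na(i)) NA_real_ else series[[s]][i]
  }, survey$year, survey$sex)
  tab <- data.frame(year = survey$year, sex = survey$sex,
                    model = model, survey = survey$prevalence_pct)
  tab$diff <- tab$model - tab$survey
  list(table = tab, max_abs_diff = max(abs(tab$diff), na.rm = TRUE))
}

# population grid <-> tidy CSV ------------------------------------------------

#' Serialize a population grid to tidy CSV
#'
#' Columns `year`, `age`, `sex`, `state`, `count`; round-trips exactly
#' through [read_population_csv()] (counts are written at full precision).
#'
#' @param grid a `population_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(grid, path) {
  df <- expand.grid(age = model_ages(), sex = model_sexes(),
                    state = smoking_states(), stringsAsFactors = FALSE)
  df$year <- grid$year
  df$count <- as.vector(grid$counts)
  utils::write.csv(df[, c("year", "age", "sex", "state", "count")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "age", "sex", "state", "count")
  if (!all(need %in% names(df))) {
    stop_validation("population CSV must have columns ", paste(need, collapse = ", "))
  }
  counts <- empty_counts()
  counts[cbind(df$age + 1L, match(df$sex, model_sexes()),
               match(df$state, smoking_states()))] <- df$count
  population_grid(df$year[1], counts)
}

# baseline directory -----------------------------------------------------------

#' Save / load a calibrated baseline directory
#'
#' The on-disk form consumed by the scenario engine: `grid.csv` (tidy
#' population grid), `fertility.csv`, `mortality.csv`, `initiation.csv`,
#' `cessation.csv`, `relapse.csv`, and `settings.json` (parameters, seed,
#' package version, config fingerprint).
#'
#' @param baseline an `endgame_baseline` (or the `baseline` element of a
#'   `calibration_result`).
#' @param dir directory (created if needed).
#' @return `dir` (or the reloaded `endgame_baseline` for the reader),
#'   invisibly for the writer.
#' @export
save_baseline <- function(baseline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_population_csv(baseline$grid, file.path(dir, "grid.csv"))
  utils::write.csv(data.frame(age = model_ages(), fertility = baseline$demo$fertility),
                   file.path(dir, "fertility.csv"), row.names = FALSE)
  wide <- function(m, value) data.frame(age = model_ages(), male = m[, 1], female = m[, 2])
  utils::write.csv(wide(baseline$demo$mortality), file.path(dir, "mortality.csv"),
                   row.names = FALSE)
  utils::write.csv(wide(baseline$rates$initiation), file.path(dir, "initiation.csv"),
                   row.names = FALSE)
  utils::write.csv(wide(baseline$rates$cessation), file.path(dir, "cessation.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(duration = former_states(),
                              male = baseline$rates$relapse[, 1],
                              female = baseline$rates$relapse[, 2]),
                   file.path(dir, "relapse.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(params = baseline$params, seed = baseline$seed,
         sex_ratio_at_birth = baseline$demo$sex_ratio_at_birth,
         mortality_multiplier = baseline$demo$mortality_multiplier,
         min_initiation_age = baseline$rates$min_initiation_age,
         max_initiation_age = baseline$rates$max_initiation_age,
         package_version = as.character(utils::packageVersion("endgamesim")),
         fingerprint = config_fingerprint(baseline[c("grid", "demo", "rates")])),
    file.path(dir, "settings.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_baseline
#' @export
load_baseline <- function(dir) {
  grid <- read_population_csv(file.path(dir, "grid.csv"))
  fert <- utils::read.csv(file.path(dir, "fertility.csv"))
  mort <- utils::read.csv(file.path(dir, "mortality.csv"))
  init <- utils::read.csv(file.path(dir, "initiation.csv"))
  cess <- utils::read.csv(file.path(dir, "cessation.csv"))
  rel <- utils::read.csv(file.path(dir, "relapse.csv"))
  st <- jsonlite::read_json(file.path(dir, "settings.json"), simplifyVector = TRUE)
  demo <- demographic_rates(fert$fertility, cbind(mort$male, mort$female),
                            st$mortality_multiplier, st$sex_ratio_at_birth)
  rates <- transition_rates(cbind(init$male, init$female),
                            cbind(cess$male, cess$female),
                            cbind(rel$male, rel$female),
                            st$min_initiation_age, st$max_initiation_age)
  structure(list(grid = grid, demo = demo, rates = rates,
                 params = st$params, seed = st$seed),
            class = "endgame_baseline")
}
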