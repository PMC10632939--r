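# Scenario engine: the seven policy-strengthening scenarios (2023--2050),
# the tobacco-free-generation initiation shutoff, and the price paths.

#' Names of the seven policy scenarios
#'
#' Status quo (2022 policy levels held), full-strength non-price policies
#' (POWE), POWE plus a one-time nominal price jump to KRW 8000 (R8000), POWE
#' plus the jump followed by 10% annual nominal increases (R10%), POWE plus
#' the tobacco-free-generation sales ban (TFG, birth cohorts after 2003), and
#' the combinations.
#'
#' @return character vector in table order.
#' @export
scenario_names <- function() {
  c("status_quo", "POWE", "POWE+R8000", "POWE+R8000+R10%",
    "POWE+TFG", "POWE+TFG+R8000", "POWE+TFG+R8000+R10%")
}

#' Current (2022) policy levels
#'
#' Clean-air laws partial (smoke-free areas designated but weakly enforced),
#' cessation support encoded at the full modeled effect (quitline, cessation
#' clinics and financial coverage are in place; see the methods vignette for
#' why the missing brief-intervention component is treated as a negligible
#' increment), strong graphic health warnings without the
#' enforcement/publicity add-on, and a partial advertising ban.
#'
#' @return a `policy_state`.
#' @export
korea_policy_2022 <- function() {
  policy_state(clean_air = "partial", cessation = "full",
               warnings = "high", warnings_enforced = FALSE,
               ad_ban = "partial", ad_ban_enforced = FALSE)
}

#' Fully strengthened (POWE) policy levels
#'
#' Complete smoke-free air laws, full cessation support, strong warnings with
#' enforcement/publicity, and a comprehensive advertising ban with
#' enforcement/publicity.
#'
#' @return a `policy_state`.
#' @export
full_policy_powe <- function() {
  policy_state(clean_air = "complete", cessation = "full",
               warnings = "high", warnings_enforced = TRUE,
               ad_ban = "comprehensive", ad_ban_enforced = TRUE)
}

#' Build one of the seven policy scenarios
#'
#' @param name one of [scenario_names()].
#' @param start_year first projection year (policies strengthen here in one
#'   step).
#' @param horizon_end last projection year.
#' @param base_price nominal retail price (KRW/pack) in the base year.
#' @param inflation annual inflation assumed after the base year.
#' @param tfg_cutoff_birth_year TFG cutoff: people born strictly after this
#'   year never initiate once the scenario starts.
#' @return object of class `endgame_scenario` holding the policy schedule
#'   (calendar year -> `policy_state`, carried forward), the price rule and
#'   the optional TFG cutoff.
#' @export
build_scenario <- function(name, start_year = 2023L, horizon_end = 2050L,
                           base_price = 4500, inflation = 0.03,
                           tfg_cutoff_birth_year = 2003L) {
  if (!name %in% scenario_names()) {
    stop_validation("unknown scenario name: ", name)
  }
  base_year <- start_year - 1L
  powe <- name != "status_quo"
  has <- function(tag) grepl(tag, name, fixed = TRUE)
  price_rule <-
    if (has("R10%")) list(type = "jump_growth", jump = 8000, growth = 0.10)
    else if (has("R8000")) list(type = "jump", jump = 8000)
    else list(type = "status_quo_nominal")
  schedule <- list()
  if (powe) schedule[[as.character(start_year)]] <- full_policy_powe()
  structure(list(
    name = name,
    base_state = korea_policy_2022(),
    policy_schedule = schedule,
    price_rule = price_rule,
    tfg_cutoff_birth_year = if (has("TFG")) as.integer(tfg_cutoff_birth_year) else NULL,
    start_year = as.integer(start_year),
    horizon_end = as.integer(horizon_end),
    base_year = base_year,
    base_price = base_price,
    inflation = inflation
  ), class = "endgame_scenario")
}

#' @export
print.endgame_scenario <- function(x, ...) {
  cat(sprintf("<endgame_scenario> %s: %d-%d, price rule %s%s\n", x$name,
              x$start_year, x$horizon_end, x$price_rule$type,
              if (!is.null(x$tfg_cutoff_birth_year))
                sprintf(", TFG cutoff %d", x$tfg_cutoff_birth_year) else ""))
  invisible(x)
}

# policy state in force in calendar year y (schedule carried forward)
state_in_year <- function(scenario, year) {
  st <- scenario$base_state
  yrs <- as.integer(names(scenario$policy_schedule))
  for (y in sort(yrs)) if (y <= year) st <- scenario$policy_schedule[[as.character(y)]]
  st
}

#' Nominal and real price paths of a scenario
#'
#' @param scenario an `endgame_scenario`.
#' @param years calendar years (may include the base year).
#' @return data.frame with `year`, `nominal`, `real` (deflated to base-year
#'   prices at the scenario's inflation rate).
#' @export
price_path <- function(scenario, years = scenario$base_year:scenario$horizon_end) {
  pr <- scenario$price_rule
  nominal <- vapply(years, function(y) {
    if (y < scenario$start_year) return(scenario$base_price)
    switch(pr$type,
      status_quo_nominal = scenario$base_price,
      jump = pr$jump,
      jump_growth = pr$jump * (1 + pr$growth)^(y - scenario$start_year))
  }, numeric(1))
  real <- deflate(nominal, scenario$base_year, years, scenario$inflation)
  data.frame(year = years, nominal = nominal, real = real)
}

#' Zero initiation for banned birth cohorts
#'
#' Under a tobacco-free-generation ban, anyone born strictly after the cutoff
#' year (`grid_year - age > cutoff`) has initiation probability 0; all other
#' rates are untouched.
#'
#' @param rates a `transition_rates` object.
#' @param grid_year calendar year of the grid being stepped.
#' @param cutoff_birth_year cutoff birth year, or `NULL` for no ban.
#' @return a `transition_rates` object.
#' @export
apply_tfg <- function(rates, grid_year, cutoff_birth_year) {
  if (is.null(cutoff_birth_year)) return(rates)
  banned <- (grid_year - model_ages()) > cutoff_birth_year
  rates$initiation[banned, ] <- 0
  rates
}

# move people between current and the 1-2y former category so that the
# current stock is multiplied by m (per age); conserves cohort totals.
# m > 1 pulls recent quitters back, capped by their number.
adjust_current_stock <- function(counts, m) {
  cur <- counts[, , 2L]
  new_cur <- cur * m
  delta <- new_cur - cur               # >0 means smokers added
  add <- pmin(pmax(delta, 0), counts[, , 3L])
  drop <- pmax(-delta, 0)
  counts[, , 2L] <- cur - drop + add
  counts[, , 3L] <- counts[, , 3L] - add + drop
  counts
}

#' Run a policy scenario
#'
#' Iterates the Markov engine one calendar year at a time from the baseline
#' (base-year) grid to the scenario horizon. Each year: (1) demography;
#' (2) smoking transitions with the baseline initiation/cessation schedules
#' scaled by the persistent policy-level multipliers (relative to the base
#' state), by this year's price multipliers, and with TFG cohorts zeroed;
#' (3) stock adjustments: the level-change prevalence multiplier in the year
#' the policy changes, and the year-on-year real-price prevalence multiplier
#' every year (smokers removed this way enter the 1--2 year former category;
#' a falling real price pulls recent quitters back). Deterministic given its
#' inputs.
#'
#' @param baseline list with elements `grid` (a `population_grid` for the
#'   base year), `demo` (`demographic_rates`) and `rates`
#'   (`transition_rates`) — e.g. from [make_synthetic_baseline()] or
#'   [calibrate()].
#' @param scenario an `endgame_scenario`.
#' @param effects a `policy_effect_table`.
#' @param min_age adult age cutoff for reported prevalence.
#' @return a `projection_series`: data.frame with `year` (base year through
#'   horizon), `male`, `female`, `total` adult prevalence in percent at full
#'   precision; the combined total weights the sexes by modelled adult
#'   population. The horizon-year grid is attached as attribute
#'   `final_grid`.
#' @export
run_scenario <- function(baseline, scenario, effects = default_policy_effects(),
                         min_age = 19L) {
  grid <- baseline$grid; demo <- baseline$demo; rates <- baseline$rates
  validate_population_grid(grid)
  if (grid$year != scenario$base_year) {
    stop_validation("baseline grid year (", grid$year,
                    ") does not match the scenario base year (", scenario$base_year, ")")
  }
  years <- scenario$start_year:scenario$horizon_end
  pp <- price_path(scenario, c(scenario$base_year, years))
  real <- setNames(pp$real, pp$year)

  # persistent level multipliers, cached per distinct state
  lm_cache <- list()
  lmult <- function(st) {
    key <- paste(unlist(st), collapse = "|")
    if (is.null(lm_cache[[key]])) {
      lm_cache[[key]] <<- level_change_multipliers(scenario$base_state, st, effects)
    }
    lm_cache[[key]]
  }

  n <- length(years) + 1L
  male <- female <- total <- numeric(n)
  male[1] <- adult_prevalence(grid, min_age, "male")
  female[1] <- adult_prevalence(grid, min_age, "female")
  total[1] <- adult_prevalence(grid, min_age, "both")

  prev_state <- scenario$base_state
  for (k in seq_along(years)) {
    y <- years[k]
    grid <- evolve_population(grid, demo, validate = FALSE)
    st <- state_in_year(scenario, y)
    lm <- lmult(st)
    pm <- price_multipliers(real[[as.character(y - 1L)]], real[[as.character(y)]],
                            effects)
    eff <- rates
    eff$initiation <- clamp(eff$initiation * lm$initiation * pm$initiation, 0, 1)
    eff$cessation <- clamp(eff$cessation * lm$cessation * pm$cessation, 0, 0.95)
    eff <- apply_tfg(eff, y, scenario$tfg_cutoff_birth_year)
    grid <- apply_smoking_transitions(grid, eff, validate = FALSE)

    sm <- pm$prevalence
    changed <- !identical(st, prev_state)
    if (changed) sm <- sm * lmult(st)$prevalence / lmult(prev_state)$prevalence
    grid$counts <- adjust_current_stock(grid$counts, sm)
    prev_state <- st

    male[k + 1] <- adult_prevalence(grid, min_age, "male")
    female[k + 1] <- adult_prevalence(grid, min_age, "female")
    total[k + 1] <- adult_prevalence(grid, min_age, "both")
  }

  out <- data.frame(year = c(scenario$base_year, years),
                    male = male, female = female, total = total)
  structure(out,
            class = c("projection_series", "data.frame"),
            scenario = scenario$name,
            final_grid = grid,
            meta = list(package_version = as.character(utils::packageVersion("endgamesim")),
                        config_hash = config_fingerprint(list(scenario, effects)),
                        min_age = min_age))
}

#' Difference between two projections at one year
#'
#' @param series_a,series_b `projection_series` sharing a horizon.
#' @param year calendar year.
#' @param sex `"male"`, `"female"` or `"total"`.
#' @return `prevalence(a) - prevalence(b)` in percentage points.
#' @export
scenario_delta <- function(series_a, series_b, year, sex = c("male", "female", "total")) {
  sex <- match.arg(sex)
  ia <- match(year, series_a$year); ib <- match(year, series_b$year)
  if (is.na(ia) || is.na(ib)) stop_validation("year ", year, " outside the projection horizon")
  series_a[[sex]][ia] - series_b[[sex]][ib]
}
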