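# Shared fixtures. The calibration is expensive (~20 s), so it is run once
# per test session and memoised, as are the seven scenario projections.

.fixture_cache <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (is.null(.fixture_cache$cal)) .fixture_cache$cal <- calibrate()
  .fixture_cache$cal
}

cached_series <- function(name) {
  key <- paste0("series::", name)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_scenario(cached_calibration()$baseline,
                                          build_scenario(name))
  }
  .fixture_cache[[key]]
}

# zero-rate schedules for toy setups
zero_demo <- function(mortality = 0, fertility_age1 = 0, srb = 0.5) {
  fert <- numeric(86)
  fert[2] <- fertility_age1          # maternal age 1 (toy)
  demographic_rates(fertility = fert,
                    mortality = matrix(mortality, 86, 2),
                    sex_ratio_at_birth = srb)
}

zero_rates <- function(initiation = 0, cessation = 0, relapse1 = 0,
                       min_age = 15L, max_age = 24L) {
  init <- matrix(0, 86, 2)
  init[(min_age + 1):(max_age + 1), ] <- initiation
  rel <- matrix(0, 5, 2)
  rel[1, ] <- relapse1
  transition_rates(init, matrix(cessation, 86, 2), rel, min_age, max_age)
}

# grid with counts placed at chosen (age, sex, state) cells
grid_with <- function(year, cells) {
  cn <- array(0, dim = c(86, 2, 7))
  for (cell in cells) cn[cell[[1]] + 1, cell[[2]], cell[[3]]] <- cell[[4]]
  population_grid(year, cn)
}

zero_effect_table <- function() {
  tab <- unclass(default_policy_effects())
  z <- function(x) if (is.list(x)) lapply(x, z) else 0
  tab$clean_air <- z(tab$clean_air)
  tab$cessation_treatment$prevalence_reduction <- 0
  tab$cessation_treatment$cessation_rate_increase <- 0
  tab$warnings <- z(tab$warnings)
  tab$ad_ban <- z(tab$ad_ban)
  tab$price_elasticity <- z(tab$price_elasticity)
  endgamesim:::validate_policy_effects(tab)
}
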