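# Core containers: the age x sex x smoking-state population grid and the
# demographic / smoking transition-rate schedules that drive it.

#' Ages tracked by the model
#'
#' Single years of age 0--84 plus a terminal, absorbing 85+ bin (reported as
#' age 85). This matches the census-table convention for cohort-component
#' population projections.
#'
#' @return integer vector `0:85`.
#' @export
model_ages <- function() 0:85

#' @rdname model_ages
#' @export
model_sexes <- function() c("male", "female")

#' Smoking states
#'
#' Never smoker, current smoker, and former smoker split into quit-duration
#' categories 1--2, 3--5, 6--10, 11--15 and >= 16 years (the classic duration
#' binning for relapse rates; the last category is absorbing).
#'
#' @return character vector of the 7 state labels.
#' @export
smoking_states <- function() {
  c("never", "current", "former_1_2", "former_3_5", "former_6_10",
    "former_11_15", "former_16p")
}

former_states <- function() smoking_states()[3:7]

empty_counts <- function() {
  array(0, dim = c(86L, 2L, 7L),
        dimnames = list(age = as.character(0:85), sex = model_sexes(),
                        state = smoking_states()))
}

#' Construct a population grid
#'
#' A `population_grid` holds non-negative person counts indexed by age
#' (0--84 plus 85+), sex, and smoking state for one calendar year. Counts need
#' not be integers: the Markov engine propagates expected (fractional) counts.
#'
#' @param year calendar year (integer scalar).
#' @param counts 86 x 2 x 7 numeric array (age x sex x state); a zero array by
#'   default. Dimnames are imposed.
#' @return object of class `population_grid`.
#' @export
population_grid <- function(year, counts = empty_counts()) {
  if (length(year) != 1L || !is.finite(year)) stop_validation("year must be a finite scalar")
  counts <- as.array(counts)
  if (!identical(dim(counts), c(86L, 2L, 7L))) {
    stop_validation("counts must be an 86 x 2 x 7 array (age x sex x state)")
  }
  dimnames(counts) <- dimnames(empty_counts())
  g <- structure(list(year = as.integer(year), counts = counts),
                 class = "population_grid")
  validate_population_grid(g)
  g
}

#' Validate a population grid
#'
#' Checks non-negativity and finiteness of all counts, and (optionally) that
#' no one below `min_initiation_age` is a current or former smoker.
#'
#' @param grid a `population_grid`.
#' @param min_initiation_age if non-`NULL`, ages strictly below it must have
#'   zero current/former counts.
#' @return the grid, invisibly; errors on violation.
#' @export
validate_population_grid <- function(grid, min_initiation_age = NULL) {
  if (!inherits(grid, "population_grid")) stop_validation("not a population_grid")
  cn <- grid$counts
  if (anyNA(cn) || any(!is.finite(cn))) stop_validation("counts contain NA or non-finite values")
  if (any(cn < 0)) stop_validation("counts must be non-negative")
  if (!is.null(min_initiation_age) && min_initiation_age > 0) {
    young <- seq_len(min_initiation_age)  # ages 0 .. min_age-1
    if (any(cn[young, , -1L] != 0)) {
      stop_validation("current/former smokers present below the minimum initiation age")
    }
  }
  invisible(grid)
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("<population_grid> year %d, total %.0f persons (%.0f male / %.0f female)\n",
              x$year, sum(x$counts),
              sum(x$counts[, "male", ]), sum(x$counts[, "female", ])))
  invisible(x)
}

#' Total population by age and sex
#'
#' @param grid a `population_grid`.
#' @return 86 x 2 matrix of counts summed over smoking states.
#' @export
total_population <- function(grid) {
  apply(grid$counts, c(1, 2), sum)
}

#' Demographic rate schedules
#'
#' @param fertility births per woman per year by maternal age (length 86,
#'   non-negative).
#' @param mortality 86 x 2 matrix of annual death probabilities by age and sex.
#' @param mortality_multiplier relative mortality factor by smoking state
#'   (length 7, positive). Defaults to 1 for every state: the model projects
#'   prevalence, not differential smoker survival, unless asked to.
#' @param sex_ratio_at_birth fraction of births that are male.
#' @return object of class `demographic_rates`.
#' @export
demographic_rates <- function(fertility, mortality,
                              mortality_multiplier = rep(1, 7),
                              sex_ratio_at_birth = 0.515) {
  fertility <- as.numeric(fertility)
  if (length(fertility) != 86L) stop_validation("fertility must have length 86")
  if (anyNA(fertility) || any(!is.finite(fertility)) || any(fertility < 0)) {
    stop_validation("fertility must be finite and non-negative")
  }
  mortality <- as.matrix(mortality)
  if (!all(dim(mortality) == c(86L, 2L))) stop_validation("mortality must be 86 x 2")
  check_prob(mortality, "mortality")
  if (length(mortality_multiplier) != 7L || any(!is.finite(mortality_multiplier)) ||
      any(mortality_multiplier <= 0)) {
    stop_validation("mortality_multiplier must be 7 positive factors")
  }
  if (sex_ratio_at_birth < 0 || sex_ratio_at_birth > 1) {
    stop_validation("sex_ratio_at_birth must lie in [0, 1]")
  }
  dimnames(mortality) <- list(age = as.character(0:85), sex = model_sexes())
  structure(list(fertility = fertility, mortality = mortality,
                 mortality_multiplier = as.numeric(mortality_multiplier),
                 sex_ratio_at_birth = sex_ratio_at_birth),
            class = "demographic_rates")
}

#' Smoking transition-rate schedules
#'
#' Annual probabilities: initiation (never -> current) by age and sex, nonzero
#' only inside the initiation window; cessation (current -> former, entering
#' the 1--2 year quit-duration category) by age and sex; relapse
#' (former -> current) by quit-duration category and sex, non-increasing in
#' duration.
#'
#' @param initiation,cessation 86 x 2 matrices of probabilities.
#' @param relapse 5 x 2 matrix (duration category x sex) of probabilities.
#' @param min_initiation_age,max_initiation_age initiation window (default
#'   ages 15--24).
#' @return object of class `transition_rates`.
#' @export
transition_rates <- function(initiation, cessation, relapse,
                             min_initiation_age = 15L,
                             max_initiation_age = 24L) {
  initiation <- as.matrix(initiation); cessation <- as.matrix(cessation)
  relapse <- as.matrix(relapse)
  if (!all(dim(initiation) == c(86L, 2L))) stop_validation("initiation must be 86 x 2")
  if (!all(dim(cessation) == c(86L, 2L))) stop_validation("cessation must be 86 x 2")
  if (!all(dim(relapse) == c(5L, 2L))) stop_validation("relapse must be 5 x 2")
  check_prob(initiation, "initiation"); check_prob(cessation, "cessation")
  check_prob(relapse, "relapse")
  outside <- c(seq_len(min_initiation_age),
               if (max_initiation_age < 85L) seq.int(max_initiation_age + 2L, 86L))
  if (any(initiation[outside, ] != 0)) {
    stop_validation("initiation must be zero outside the initiation window")
  }
  if (any(diff(relapse[, 1]) > 1e-12) || any(diff(relapse[, 2]) > 1e-12)) {
    stop_validation("relapse must be non-increasing in quit duration")
  }
  dimnames(initiation) <- dimnames(cessation) <-
    list(age = as.character(0:85), sex = model_sexes())
  dimnames(relapse) <- list(duration = former_states(), sex = model_sexes())
  structure(list(initiation = initiation, cessation = cessation,
                 relapse = relapse,
                 min_initiation_age = as.integer(min_initiation_age),
                 max_initiation_age = as.integer(max_initiation_age)),
            class = "transition_rates")
}

#' Adult smoking prevalence of a population grid
#'
#' @param grid a `population_grid`.
#' @param min_age lower age bound for "adult" (default 19, completed years).
#' @param sex `"male"`, `"female"`, or `"both"` (population-weighted).
#' @return percentage in `[0, 100]`: 100 x current smokers aged >= `min_age`
#'   divided by the population aged >= `min_age`.
#' @export
adult_prevalence <- function(grid, min_age = 19L, sex = c("both", "male", "female")) {
  sex <- match.arg(sex)
  if (min_age < 0 || min_age > 85) stop_validation("min_age outside the age range")
  rows <- (min_age + 1L):86L
  sel <- if (sex == "both") 1:2 else match(sex, model_sexes())
  num <- sum(grid$counts[rows, sel, "current"])
  den <- sum(grid$counts[rows, sel, ])
  if (den <= 0) stop_validation("no population in the requested adult stratum")
  100 * num / den
}
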