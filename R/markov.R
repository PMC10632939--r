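# The discrete-time Markov engine. One call of evolve_population() followed by
# one call of apply_smoking_transitions() advances the model one calendar year
# (demography first, then smoking transitions; policy multipliers are layered
# on top by the scenario engine).

#' Advance the population one year by fertility and mortality
#'
#' Each age-`a` cohort survives with probability
#' `1 - mortality(a, sex) * mortality_multiplier(state)` and moves to age
#' `a + 1`; the 85+ bin accumulates survivors from age 84 and from itself.
#' Births are computed from the post-survival female age distribution
#' (still indexed by their start-of-year age), split by the sex ratio at
#' birth, and enter at age 0 as never smokers. Smoking-state proportions
#' within a cohort are untouched: state transitions are applied separately by
#' [apply_smoking_transitions()].
#'
#' @param grid a `population_grid` (calendar year `y`).
#' @param demo a `demographic_rates` object.
#' @param validate run the (cheap, but per-step) invariant checks.
#' @return a `population_grid` for calendar year `y + 1`.
#' @export
evolve_population <- function(grid, demo, validate = TRUE) {
  if (validate) {
    validate_population_grid(grid)
    if (!inherits(demo, "demographic_rates")) stop_validation("demo must be demographic_rates")
  }
  cn <- grid$counts
  # survival probability by (age, sex, state)
  psurv <- 1 - outer(demo$mortality, demo$mortality_multiplier)
  if (any(psurv < 0)) stop_validation("mortality * multiplier exceeds 1 for some state")
  surv <- cn * psurv

  out <- empty_counts()
  out[2:86, , ] <- surv[1:85, , ]
  out[86, , ] <- out[86, , ] + surv[86, , ]

  females <- rowSums(surv[, 2L, , drop = FALSE], dims = 1)
  births <- sum(demo$fertility * females)
  out[1L, 1L, 1L] <- births * demo$sex_ratio_at_birth
  out[1L, 2L, 1L] <- births * (1 - demo$sex_ratio_at_birth)

  structure(list(year = grid$year + 1L, counts = out), class = "population_grid")
}

#' Apply one year of smoking-state transitions
#'
#' Within each (age, sex) cohort, computed simultaneously from the
#' start-of-year state: never smokers initiate with the initiation
#' probability; current smokers quit with the cessation probability and enter
#' the 1--2 year quit-duration category; former smokers relapse with the
#' duration-specific relapse probability; non-relapsing former smokers
#' advance one quit-duration category (>= 16 years is absorbing). Cohort
#' totals are conserved exactly.
#'
#' @param grid a `population_grid`.
#' @param rates a `transition_rates` object (probabilities may already carry
#'   policy multipliers).
#' @param validate run invariant checks.
#' @return a `population_grid` for the same calendar year with updated states.
#' @export
apply_smoking_transitions <- function(grid, rates, validate = TRUE) {
  if (validate) {
    validate_population_grid(grid)
    if (!inherits(rates, "transition_rates")) stop_validation("rates must be transition_rates")
  }
  cn <- grid$counts
  N <- cn[, , 1L]; C <- cn[, , 2L]
  f1 <- cn[, , 3L]; f2 <- cn[, , 4L]; f3 <- cn[, , 5L]
  f4 <- cn[, , 6L]; f5 <- cn[, , 7L]

  # relapse rates expanded to age x sex
  r <- rates$relapse
  r1 <- matrix(r[1L, ], 86L, 2L, byrow = TRUE)
  r2 <- matrix(r[2L, ], 86L, 2L, byrow = TRUE)
  r3 <- matrix(r[3L, ], 86L, 2L, byrow = TRUE)
  r4 <- matrix(r[4L, ], 86L, 2L, byrow = TRUE)
  r5 <- matrix(r[5L, ], 86L, 2L, byrow = TRUE)

  I <- N * rates$initiation
  Q <- C * rates$cessation
  relapsed <- f1 * r1 + f2 * r2 + f3 * r3 + f4 * r4 + f5 * r5

  out <- cn
  out[, , 1L] <- N - I
  out[, , 2L] <- C - Q + I + relapsed
  out[, , 3L] <- Q
  out[, , 4L] <- f1 * (1 - r1)
  out[, , 5L] <- f2 * (1 - r2)
  out[, , 6L] <- f3 * (1 - r3)
  out[, , 7L] <- f4 * (1 - r4) + f5 * (1 - r5)

  if (any(out < -1e-9)) {
    stop("internal error: negative count after smoking transitions (rate > 1 or ordering bug)")
  }
  out[out < 0] <- 0
  structure(list(year = grid$year, counts = out), class = "population_grid")
}

#' Project the raw (policy-free) model
#'
#' Iterates demography and smoking transitions with fixed rate schedules and
#' no policy module — the cohort-model counterpart of [microsim_oracle()].
#'
#' @param grid starting `population_grid`.
#' @param demo `demographic_rates`.
#' @param rates `transition_rates`.
#' @param n_years number of annual steps.
#' @param min_age adult age cutoff for the reported prevalences.
#' @return data.frame with columns `year`, `male`, `female`, `total`
#'   (adult prevalence, %), starting at the input year.
#' @export
project_raw <- function(grid, demo, rates, n_years, min_age = 19L) {
  years <- grid$year + 0:n_years
  male <- female <- total <- numeric(n_years + 1L)
  # toy setups may have an empty sex stratum; report NA there rather than fail
  safe_prev <- function(g, sex) {
    tryCatch(adult_prevalence(g, min_age, sex), error = function(e) NA_real_)
  }
  g <- grid
  male[1] <- safe_prev(g, "male"); female[1] <- safe_prev(g, "female")
  total[1] <- safe_prev(g, "both")
  for (k in seq_len(n_years)) {
    g <- evolve_population(g, demo, validate = FALSE)
    g <- apply_smoking_transitions(g, rates, validate = FALSE)
    male[k + 1] <- safe_prev(g, "male")
    female[k + 1] <- safe_prev(g, "female")
    total[k + 1] <- safe_prev(g, "both")
  }
  data.frame(year = years, male = male, female = female, total = total)
}
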