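# Individual-based simulation used as an independent oracle for the cohort
# engine: identical per-year transition probabilities, applied to sampled
# agents instead of expected counts.

#' Individual-based (microsimulation) oracle
#'
#' Samples `n_agents` agents from the population grid and simulates them
#' forward with the same annual death, initiation, cessation and relapse
#' probabilities the cohort engine uses (no policy module). Births add new
#' never-smoking agents at the grid's person-per-agent weight. Agreement
#' with [project_raw()] within Monte-Carlo error is the cohort engine's
#' principal correctness check.
#'
#' @param grid starting `population_grid`.
#' @param demo `demographic_rates`.
#' @param rates `transition_rates`.
#' @param n_agents number of simulated agents (>= 1e4 for useful precision).
#' @param n_years annual steps to simulate.
#' @param seed RNG seed.
#' @param min_age adult age cutoff for reported prevalence.
#' @return data.frame with `year`, `male`, `female`, `total` adult
#'   prevalences (%) and their Monte-Carlo standard errors `se_male`,
#'   `se_female`, `se_total` (binomial, in percentage points).
#' @export
microsim_oracle <- function(grid, demo, rates, n_agents = 1e5, n_years = 10,
                            seed = 1L, min_age = 19L) {
  if (n_agents < 1e4) stop_validation("n_agents must be at least 1e4")
  validate_population_grid(grid)
  set.seed(seed)

  cells <- which(grid$counts > 0, arr.ind = TRUE)
  probs <- grid$counts[cells]
  idx <- sample.int(nrow(cells), n_agents, replace = TRUE, prob = probs)
  age <- as.integer(cells[idx, 1L]) - 1L
  sex <- as.integer(cells[idx, 2L])          # 1 male, 2 female
  state <- as.integer(cells[idx, 3L])        # index into smoking_states()
  weight <- sum(grid$counts) / n_agents      # persons per agent

  prev_rows <- function() {
    ad <- age >= min_age
    res <- numeric(6)
    for (s in 1:2) {
      n_ad <- sum(ad & sex == s)
      p <- if (n_ad > 0) mean(state[ad & sex == s] == 2L) else NA_real_
      res[s] <- 100 * p
      res[s + 3] <- 100 * sqrt(p * (1 - p) / n_ad)
    }
    n_ad <- sum(ad)
    p <- mean(state[ad] == 2L)
    res[3] <- 100 * p
    res[6] <- 100 * sqrt(p * (1 - p) / n_ad)
    res
  }

  out <- matrix(NA_real_, n_years + 1L, 6L)
  out[1L, ] <- prev_rows()

  for (k in seq_len(n_years)) {
    # survival, mirroring the cohort engine's mortality step
    q <- demo$mortality[cbind(age + 1L, sex)] * demo$mortality_multiplier[state]
    alive <- stats::runif(length(age)) >= q
    age <- age[alive]; sex <- sex[alive]; state <- state[alive]
    age <- pmin(age + 1L, 85L)

    # births from the post-survival female age distribution (pre-aging ages
    # are age - 1 now; the cohort engine indexes fertility by start-of-year
    # age, so shift back)
    fem_ages <- age[sex == 2L] - 1L
    lambda <- sum(demo$fertility[pmax(fem_ages, 0L) + 1L])
    n_born <- stats::rpois(1L, lambda)
    if (n_born > 0) {
      born_male <- stats::rbinom(1L, n_born, demo$sex_ratio_at_birth)
      age <- c(age, rep(0L, n_born))
      sex <- c(sex, rep(1L, born_male), rep(2L, n_born - born_male))
      state <- c(state, rep(1L, n_born))
    }

    # smoking transitions from the common start-of-year snapshot
    u <- stats::runif(length(age))
    ai <- cbind(age + 1L, sex)
    new_state <- state
    nv <- state == 1L
    new_state[nv & u < rates$initiation[ai]] <- 2L
    cu <- state == 2L
    new_state[cu & u < rates$cessation[ai]] <- 3L
    for (d in 1:5) {
      fo <- state == d + 2L
      rel <- u < rates$relapse[cbind(rep(d, length(age)), sex)]
      new_state[fo & rel] <- 2L
      if (d < 5) new_state[fo & !rel] <- d + 3L  # advance one duration category
    }
    state <- new_state
    out[k + 1L, ] <- prev_rows()
  }

  data.frame(year = grid$year + 0:n_years,
             male = out[, 1], female = out[, 2], total = out[, 3],
             se_male = out[, 4], se_female = out[, 5], se_total = out[, 6],
             n_agents = n_agents * 1, weight = weight)
}
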