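# Synthetic baseline and calibration. The measured Korean inputs behind the
# original projections (census population, fertility/mortality tables, and
# survey-derived initiation/quit/relapse schedules) are not published, so the
# package generates a stylized stand-in and calibrates a low-dimensional
# parameter vector until the status-quo projection reproduces the published
# anchor trajectories. Everything here is synthetic by construction and is
# labelled as such.

#' Shape parameters of the synthetic baseline
#'
#' The free knobs of the stylized Korea-like baseline. Initiation is a
#' Gaussian bump over ages 15--24 (`init_scale_*` is the peak annual
#' probability, `init_peak_age` its mode); cessation rises linearly with age
#' (`cess_scale_*` is the rate at the oldest age); relapse declines with quit
#' duration from a fixed profile scaled by `relapse_scale`.
#'
#' @param init_scale_male,init_scale_female peak annual initiation
#'   probability by sex.
#' @param cess_scale_male,cess_scale_female cessation scale by sex.
#' @param init_peak_age age at which initiation peaks (inside 15--24).
#' @param relapse_scale multiplier on the duration-declining relapse profile.
#' @return named list of parameters.
#' @export
baseline_params <- function(init_scale_male = 0.055, init_scale_female = 0.007,
                            cess_scale_male = 0.045, cess_scale_female = 0.055,
                            init_peak_age = 17, relapse_scale = 1) {
  list(init_scale_male = init_scale_male, init_scale_female = init_scale_female,
       cess_scale_male = cess_scale_male, cess_scale_female = cess_scale_female,
       init_peak_age = init_peak_age, relapse_scale = relapse_scale)
}

# fixed stylized shapes -------------------------------------------------------

# age pyramid: thin child cohorts, a working-age bulge, survival decay in old
# age (low-fertility East Asian population shape)
synthetic_age_pyramid <- function(total_pop) {
  a <- model_ages()
  w <- 0.52 + 0.48 * exp(-(a - 48)^2 / (2 * 20^2))
  w[a < 20] <- w[a < 20] * (0.55 + 0.45 * (a[a < 20] / 20))
  w[a > 62] <- w[a > 62] * exp(-0.045 * (a[a > 62] - 62))
  male_share <- 0.512 - 0.0012 * pmax(0, a - 50)
  pop <- total_pop * w / sum(w)
  cbind(male = pop * male_share, female = pop * (1 - male_share))
}

# flat-plus-senescent (Gompertz) mortality; heavier for males; the 85+ bin
# carries an aggregate turnover rate
synthetic_mortality <- function() {
  a <- model_ages()
  base <- 4e-4 + 2.2e-5 * exp(0.092 * a)
  m <- cbind(male = clamp(base * 1.35, 0, 1), female = clamp(base * 0.85, 0, 1))
  m[86, ] <- c(0.13, 0.11)
  m
}

# below-replacement fertility (TFR ~ 0.85) centred at maternal age 31
synthetic_fertility <- function(tfr = 0.85) {
  a <- model_ages()
  f <- exp(-(a - 31)^2 / (2 * 5^2))
  f[a < 18 | a > 45] <- 0
  tfr * f / sum(f)
}

synthetic_transition_rates <- function(params) {
  a <- model_ages()
  init_shape <- exp(-(a - params$init_peak_age)^2 / (2 * 3^2))
  init_shape[a < 15 | a > 24] <- 0
  initiation <- cbind(male = clamp(params$init_scale_male * init_shape, 0, 1),
                      female = clamp(params$init_scale_female * init_shape, 0, 1))
  cess_shape <- ifelse(a >= 15, 0.5 + 0.5 * (a - 15) / 70, 0)
  cessation <- cbind(male = clamp(params$cess_scale_male * cess_shape, 0, 0.9),
                     female = clamp(params$cess_scale_female * cess_shape, 0, 0.9))
  rel <- clamp(params$relapse_scale * c(0.12, 0.06, 0.03, 0.015, 0.008), 0, 1)
  transition_rates(initiation, cessation, cbind(male = rel, female = rel))
}

# 2022 current-smoker age profile shape (relative): ramps in over ages 15-25,
# plateaus through midlife, tapers at old age. The absolute level is set by
# scaling to the target adult prevalence.
current_profile_shape <- function() {
  a <- model_ages()
  ramp <- clamp((a - 15) / 10, 0, 1)
  taper <- ifelse(a > 55, 1 - 0.55 * (a - 55) / 30, 1)
  ramp * clamp(taper, 0.45, 1)
}

# former smokers in the base year, as a multiple of the current-smoker
# fraction rising with age (quitting accumulates over a smoking career);
# tying former to current keeps the two stocks proportionate per sex and
# makes a zero-prevalence target an all-never population
former_age_multiple <- function() {
  clamp(0.04 * (model_ages() - 24), 0, 1.3)
}

former_duration_split <- function(age) {
  if (age < 30) c(0.40, 0.30, 0.20, 0.10, 0.00)
  else if (age < 45) c(0.20, 0.20, 0.25, 0.20, 0.15)
  else c(0.08, 0.12, 0.20, 0.20, 0.40)
}

#' Generate the stylized synthetic baseline
#'
#' Builds a smooth Korea-like age pyramid, flat-plus-senescent mortality,
#' below-replacement fertility, parametric initiation/cessation/relapse
#' schedules, and a base-year smoking-state distribution whose adult
#' prevalence matches `start_prevalence` exactly (the current-smoker age
#' profile is scaled linearly per sex). The construction is deterministic;
#' `seed` is recorded for provenance only.
#'
#' @param params shape parameters from [baseline_params()].
#' @param start_prevalence named vector: target adult prevalence (%) by sex
#'   in the base year.
#' @param year base calendar year of the grid.
#' @param total_pop total synthetic population size (prevalences are
#'   scale-free; the default keeps arithmetic well away from underflow).
#' @param seed recorded in the result for reproducibility bookkeeping.
#' @return list of class `endgame_baseline` with elements `grid`, `demo`,
#'   `rates`, `params`, `seed`.
#' @export
make_synthetic_baseline <- function(params = baseline_params(),
                                    start_prevalence = c(male = 35.3, female = 3.6),
                                    year = 2022L, total_pop = 1e6, seed = NULL) {
  if (any(start_prevalence < 0) || any(start_prevalence > 100)) {
    stop_validation("start_prevalence must lie in [0, 100]")
  }
  pop <- synthetic_age_pyramid(total_pop)
  demo <- demographic_rates(fertility = synthetic_fertility(),
                            mortality = synthetic_mortality())
  rates <- synthetic_transition_rates(params)

  counts <- empty_counts()
  shape <- current_profile_shape()
  adult <- 20:86                      # ages >= 19
  split <- t(vapply(model_ages(), former_duration_split, numeric(5)))
  for (s in 1:2) {
    sexname <- model_sexes()[s]
    target <- start_prevalence[[sexname]] / 100
    p_a <- pop[, s]
    denom <- sum(p_a[adult] * shape[adult])
    k <- if (denom > 0) target * sum(p_a[adult]) / denom else 0
    cur_frac <- clamp(k * shape, 0, 0.95)
    fo_frac <- cur_frac * former_age_multiple()
    over <- cur_frac + fo_frac > 0.98  # keep a never-smoker remainder
    fo_frac[over] <- 0.98 - cur_frac[over]
    counts[, s, 2L] <- p_a * cur_frac
    fo <- p_a * fo_frac
    counts[, s, 3:7] <- fo * split
    counts[, s, 1L] <- p_a - counts[, s, 2L] - rowSums(counts[, s, 3:7, drop = FALSE])
  }
  grid <- population_grid(year, counts)

  # exactness check of the scaled profile (linear scaling can clip only if the
  # target is infeasible for the shape)
  for (s in model_sexes()) {
    got <- adult_prevalence(grid, 19L, s)
    if (abs(got - start_prevalence[[s]]) > 1e-6) {
      stop_validation("infeasible start prevalence for ", s,
                      " (requested ", start_prevalence[[s]], ", achievable ", got, ")")
    }
  }
  structure(list(grid = grid, demo = demo, rates = rates,
                 params = params, seed = seed),
            class = "endgame_baseline")
}

#' Published status-quo anchor trajectories
#'
#' The base-year adult prevalences and the status-quo projection anchors the
#' synthetic baseline is calibrated against.
#'
#' @param path CSV with columns `year`, `sex`, `prevalence_pct`; defaults to
#'   the file shipped in `extdata`. Ignored when `data` is given.
#' @param data optional data.frame in the same schema (e.g. anchors generated
#'   from a known synthetic truth for recovery experiments).
#' @return object of class `calibration_anchors`: list with
#'   `start_prevalence` (base-year, by sex), `years` (anchor years), and
#'   `male` / `female` anchor vectors (%).
#' @export
calibration_anchors <- function(path = system.file("extdata", "status_quo_anchors.csv",
                                                   package = "endgamesim"),
                                data = NULL) {
  df <- if (is.null(data)) utils::read.csv(path, stringsAsFactors = FALSE) else data
  need <- c("year", "sex", "prevalence_pct")
  if (!all(need %in% names(df))) stop_validation("anchor CSV must have columns ", paste(need, collapse = ", "))
  base_year <- min(df$year)
  anchor_years <- sort(unique(df$year[df$year > base_year]))
  pick <- function(sex, years) {
    v <- df$prevalence_pct[df$sex == sex][match(years, df$year[df$sex == sex])]
    if (anyNA(v)) stop_validation("anchors must cover both sexes at every anchor year")
    setNames(v, years)
  }
  start <- c(male = unname(pick("male", base_year)),
             female = unname(pick("female", base_year)))
  male <- pick("male", anchor_years); female <- pick("female", anchor_years)
  if (any(c(start, male, female) <= 0) || any(c(start, male, female) >= 100)) {
    stop_validation("anchor prevalences must lie strictly inside (0, 100)")
  }
  if (any(diff(c(start[["male"]], male)) > 0)) {
    stop_validation("male status-quo anchor path must be non-increasing")
  }
  structure(list(start_prevalence = start, base_year = base_year,
                 years = anchor_years, male = male, female = female),
            class = "calibration_anchors")
}

# parameter vector <-> unconstrained optimizer coordinates.
# Each parameter is box-bounded to an epidemiologically plausible range
# (annual initiation probabilities that cumulate to realistic young-adult
# uptake, cessation rates of a few percent per year, relapse within a factor
# of a few of the reference profile) and mapped to the real line by a logit;
# the bounds keep the fit from wandering into corners that match the
# aggregate anchors with implausible age dynamics.
free_param_names <- function() names(baseline_params())

param_bounds <- function() {
  list(init_scale_male = c(0.005, 0.12),
       init_scale_female = c(5e-4, 0.01),
       cess_scale_male = c(0.005, 0.20),
       cess_scale_female = c(0.005, 0.20),
       init_peak_age = c(15, 24),
       relapse_scale = c(0.05, 3))
}

params_to_theta <- function(params, free) {
  b <- param_bounds()
  vapply(free, function(nm) {
    lo <- b[[nm]][1]; hi <- b[[nm]][2]
    stats::qlogis((clamp(params[[nm]], lo + 1e-9, hi - 1e-9) - lo) / (hi - lo))
  }, numeric(1))
}

theta_to_params <- function(theta, free, fixed_params) {
  b <- param_bounds()
  p <- fixed_params
  for (i in seq_along(free)) {
    nm <- free[i]
    lo <- b[[nm]][1]; hi <- b[[nm]][2]
    p[[nm]] <- lo + (hi - lo) * stats::plogis(theta[i])
  }
  p
}

#' Calibrate the synthetic baseline to the anchor trajectories
#'
#' Adjusts the shape parameters by derivative-free simplex (Nelder--Mead with
#' restart) so the status-quo projection matches the anchors, minimizing the
#' equally weighted sum of squared deviations (in squared percentage points)
#' over both sexes' anchor years. The base-year prevalence is exact by
#' construction, so only later anchors enter the loss.
#'
#' @param anchors a `calibration_anchors` object.
#' @param params0 starting parameters.
#' @param settings list: `maxit` (evaluation budget per stage, default 600),
#'   `restarts` (default 1), `fixed` (character vector of parameter names
#'   held at their `params0` value), `loss_target` (default 0.5 squared
#'   percentage points, summed).
#' @param effects policy-effect table used for the status-quo run (the
#'   status quo still carries the inflation-driven real-price drift).
#' @return object of class `calibration_result`: `params`, `baseline` (the
#'   calibrated [make_synthetic_baseline()] output), `loss`, `converged`
#'   (loss at or below `loss_target`; non-convergence is flagged, not an
#'   error), `under_determined` (fewer anchor points than free parameters),
#'   `fit` (anchor vs fitted table), `settings`.
#' @export
calibrate <- function(anchors = calibration_anchors(),
                      params0 = baseline_params(),
                      settings = list(),
                      effects = default_policy_effects()) {
  if (!inherits(anchors, "calibration_anchors")) stop_validation("anchors invalid")
  maxit <- settings$maxit %||% 600
  restarts <- settings$restarts %||% 1
  fixed <- settings$fixed %||% character()
  loss_target <- settings$loss_target %||% 0.5
  free <- setdiff(free_param_names(), fixed)
  if (length(free) == 0L) stop_validation("no free parameters to calibrate")

  n_anchor_years <- length(anchors$years)
  scen <- build_scenario("status_quo",
                         start_year = anchors$base_year + 1L,
                         horizon_end = if (n_anchor_years > 0L) max(anchors$years)
                                       else anchors$base_year + 1L)
  n_eval <- 0L
  loss_fn <- function(theta) {
    n_eval <<- n_eval + 1L
    p <- theta_to_params(theta, free, params0)
    bl <- tryCatch(make_synthetic_baseline(p, anchors$start_prevalence,
                                           year = anchors$base_year),
                   error = function(e) NULL)
    if (is.null(bl)) return(1e6)
    proj <- run_scenario(bl, scen, effects)
    idx <- match(anchors$years, proj$year)
    sum((proj$male[idx] - anchors$male)^2) +
      sum((proj$female[idx] - anchors$female)^2)
  }

  n_anchor <- 2L * n_anchor_years
  under_determined <- n_anchor < length(free)
  theta <- params_to_theta(params0, free)
  best <- list(par = theta,
               value = if (n_anchor > 0L) loss_fn(theta) else 0)
  if (n_anchor > 0L) {
    for (r in 0:restarts) {
      opt <- stats::optim(best$par, loss_fn, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10))
      if (opt$value < best$value) best <- opt
    }
  }
  params <- theta_to_params(best$par, free, params0)
  baseline <- make_synthetic_baseline(params, anchors$start_prevalence,
                                      year = anchors$base_year)
  proj <- run_scenario(baseline, scen, effects)
  idx <- match(anchors$years, proj$year)
  fit <- data.frame(year = rep(anchors$years, 2),
                    sex = rep(c("male", "female"), each = length(anchors$years)),
                    anchor = c(anchors$male, anchors$female),
                    fitted = c(proj$male[idx], proj$female[idx]))
  fit$residual <- fit$fitted - fit$anchor
  structure(list(params = params, baseline = baseline, loss = best$value,
                 converged = best$value <= loss_target, fit = fit,
                 under_determined = under_determined,
                 n_eval = n_eval,
                 settings = list(maxit = maxit, restarts = restarts,
                                 fixed = fixed, loss_target = loss_target)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> loss %.4g (%s), %d evaluations, max |residual| %.3f %%p\n",
              x$loss, if (x$converged) "converged" else "NOT converged",
              x$n_eval, max(abs(x$fit$residual))))
  invisible(x)
}
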