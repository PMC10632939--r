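# One-way and probabilistic sensitivity analysis over the policy-effect
# parameters, and the bias-corrected percentile interval.

#' Scale one policy family's effect sizes
#'
#' Multiplies every effect fraction of the component by `factor` (for the
#' price component: every elasticity), clamping fractions to `[0, 0.999]`.
#'
#' @param effects a `policy_effect_table`.
#' @param component one of `"P"`, `"O"`, `"W"`, `"E"`, `"R"`.
#' @param factor positive scale.
#' @return a scaled `policy_effect_table`.
#' @export
scale_effect_table <- function(effects, component, factor) {
  factor <- unname(factor)
  sc <- function(x) clamp(x * factor, 0, 0.999)
  tab <- unclass(effects)
  switch(component,
    P = tab$clean_air <- lapply(tab$clean_air, sc),
    O = {
      tab$cessation_treatment$prevalence_reduction <-
        sc(tab$cessation_treatment$prevalence_reduction)
      tab$cessation_treatment$cessation_rate_increase <-
        tab$cessation_treatment$cessation_rate_increase * factor
    },
    W = {
      tab$warnings$high <- lapply(tab$warnings$high, sc)
      tab$warnings$low <- lapply(tab$warnings$low, sc)
      tab$warnings$enforcement_publicity <- sc(tab$warnings$enforcement_publicity)
    },
    E = {
      tab$ad_ban$comprehensive <- lapply(tab$ad_ban$comprehensive, sc)
      tab$ad_ban$complete <- lapply(tab$ad_ban$complete, sc)
      tab$ad_ban$partial <- lapply(tab$ad_ban$partial, sc)
      tab$ad_ban$enforcement_publicity <- sc(tab$ad_ban$enforcement_publicity)
    },
    R = tab$price_elasticity <- lapply(tab$price_elasticity, `*`, factor),
    stop_validation("unknown component: ", component)
  )
  validate_policy_effects(tab)
}

#' One-way sensitivity run
#'
#' Scales every effect size of one policy family by `1 + delta` and reruns
#' the scenario on the same calibrated baseline.
#'
#' @param baseline calibrated baseline (as for [run_scenario()]).
#' @param scenario an `endgame_scenario` (conventionally the combined
#'   endgame scenario).
#' @param component `"P"`, `"O"`, `"W"`, `"E"` or `"R"`.
#' @param delta relative perturbation in `[-0.9, 0.9]`.
#' @param effects unperturbed `policy_effect_table`.
#' @return a `projection_series`.
#' @export
one_way <- function(baseline, scenario, component, delta,
                    effects = default_policy_effects()) {
  if (delta < -0.9 || delta > 0.9) stop_validation("delta must lie in [-0.9, 0.9]")
  run_scenario(baseline, scenario, scale_effect_table(effects, component, 1 + delta))
}

#' Full one-way sensitivity grid
#'
#' @param baseline calibrated baseline.
#' @param scenario scenario to perturb.
#' @param components policy families.
#' @param deltas perturbation grid.
#' @param years report years.
#' @param effects unperturbed table.
#' @return data.frame with columns `component`, `delta`, `year`, `male`,
#'   `female`, `total` (adult prevalence, %).
#' @export
one_way_grid <- function(baseline, scenario = build_scenario("POWE+TFG+R8000+R10%"),
                         components = c("P", "O", "W", "E", "R"),
                         deltas = c(-0.5, -0.25, 0, 0.25, 0.5),
                         years = c(2030, 2050),
                         effects = default_policy_effects()) {
  rows <- list()
  for (comp in components) {
    for (d in deltas) {
      ser <- if (d == 0) run_scenario(baseline, scenario, effects)
             else one_way(baseline, scenario, comp, d, effects)
      idx <- match(years, ser$year)
      rows[[length(rows) + 1L]] <-
        data.frame(component = comp, delta = d, year = years,
                   male = ser$male[idx], female = ser$female[idx],
                   total = ser$total[idx])
    }
  }
  do.call(rbind, rows)
}

# mean-1 scale factor on [0.5, 1.5]: 0.5 + Beta(a, a), with a chosen so the
# standard deviation is `sd`
beta_scale_draws <- function(n, sd) {
  if (sd <= 0 || sd >= 0.5) stop_validation("sd must lie in (0, 0.5)")
  a <- (1 / (4 * sd^2) - 1) / 2
  0.5 + stats::rbeta(n, a, a)
}

#' Probabilistic sensitivity analysis
#'
#' Each draw samples an independent scale factor per policy family (P, O, W,
#' E, R) from a beta distribution rescaled to `[0.5, 1.5]` with mean 1,
#' scales the whole family by it, and reruns the scenario. Confidence
#' intervals use the bias-corrected percentile method around the unperturbed
#' point estimate.
#'
#' @param baseline calibrated baseline.
#' @param scenario scenario to rerun per draw.
#' @param n_draws number of parameter draws (>= 2; 1000 in the full
#'   analysis).
#' @param seed RNG seed.
#' @param sd standard deviation of the scale factors (default 0.125).
#' @param report_years calendar years to summarize.
#' @param level confidence level.
#' @param effects unperturbed table.
#' @return object of class `psa_result`: `summary` data.frame (`year`,
#'   `sex`, `point`, `lower`, `upper`), the `draws` matrix
#'   (n_draws x year/sex combinations), `n_draws`, `seed`, `sd`.
#' @export
psa <- function(baseline, scenario, n_draws = 1000L, seed = 1L, sd = 0.125,
                report_years = c(2030, 2050), level = 0.95,
                effects = default_policy_effects()) {
  if (n_draws < 2) stop_validation("n_draws must be >= 2")
  set.seed(seed)
  fams <- c("P", "O", "W", "E", "R")
  scales <- matrix(beta_scale_draws(n_draws * length(fams), sd),
                   nrow = n_draws, dimnames = list(NULL, fams))
  base_ser <- run_scenario(baseline, scenario, effects)
  idx <- match(report_years, base_ser$year)
  if (anyNA(idx)) stop_validation("report year outside the scenario horizon")
  cols <- as.vector(outer(c("male", "female", "total"), report_years,
                          function(s, y) paste0(s, "_", y)))
  draws <- matrix(NA_real_, n_draws, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n_draws)) {
    tab <- effects
    for (f in fams) tab <- scale_effect_table(tab, f, scales[i, f])
    ser <- run_scenario(baseline, scenario, tab)
    draws[i, ] <- c(rbind(ser$male[idx], ser$female[idx], ser$total[idx]))
  }
  point <- c(rbind(base_ser$male[idx], base_ser$female[idx], base_ser$total[idx]))
  names(point) <- cols
  ci <- t(vapply(cols, function(cl) bc_percentile(draws[, cl], point[[cl]], level),
                 numeric(2)))
  summary <- data.frame(
    year = rep(report_years, each = 3),
    sex = rep(c("male", "female", "total"), times = length(report_years)),
    point = unname(point), lower = ci[, 1], upper = ci[, 2])
  structure(list(summary = summary, draws = draws, n_draws = n_draws,
                 seed = seed, sd = sd, level = level),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d, scale sd %.3f)\n",
              x$n_draws, x$seed, x$sd))
  print(transform(x$summary,
                  point = round_half_up(point, 1),
                  lower = round_half_up(lower, 2),
                  upper = round_half_up(upper, 2)))
  invisible(x)
}

#' Bias-corrected percentile interval
#'
#' The bias correction `z0 = qnorm(mean(draws < point))` shifts the quantile
#' positions to `pnorm(2 * z0 +/- z_alpha/2)`. When exactly half the draws
#' fall below the point estimate (`z0 = 0`) this reduces to the plain
#' percentile interval. If all draws fall on one side of the point, `z0` is
#' infinite and the function falls back to the plain percentile interval
#' with a warning.
#'
#' @param draws numeric vector of bootstrap/Monte-Carlo draws.
#' @param point point estimate.
#' @param level confidence level (default 0.95; `z_alpha/2` = 1.959964).
#' @return named vector `c(lower, upper)`.
#' @export
bc_percentile <- function(draws, point, level = 0.95) {
  if (length(draws) < 2) stop_validation("need at least 2 draws")
  alpha <- 1 - level
  zc <- stats::qnorm(1 - alpha / 2)
  p_below <- mean(draws < point)
  if (p_below <= 0 || p_below >= 1) {
    warning("all draws on one side of the point estimate; using plain percentiles")
    q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    return(c(lower = q[1], upper = q[2]))
  }
  z0 <- stats::qnorm(p_below)
  probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
  q <- stats::quantile(draws, probs, names = FALSE)
  c(lower = q[1], upper = q[2])
}
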