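# Policy-effect module: converts policy-level changes and real price changes
# into multiplicative adjustments of prevalence, initiation and cessation.
#
# Conventions (the established tobacco-policy simulation lineage):
#   * an effect fraction PE reduces prevalence/initiation via the factor
#     (1 - PE); a cessation effect CE scales the quit rate via (1 + CE);
#   * a level change old -> new therefore multiplies by
#     (1 - PE_new) / (1 - PE_old)  (and (1 + CE_new) / (1 + CE_old));
#   * independent components combine multiplicatively, which keeps combined
#     effects below 1 and makes level changes path-independent;
#   * the prevalence multiplier of a level change is applied once, as a stock
#     adjustment in the year of the change (quitting smokers enter the 1--2
#     year former category), while initiation/cessation multipliers persist.

#' Load the policy-effect table
#'
#' Reads the versioned YAML shipped with the package (or a user override)
#' holding the MPOWER effect sizes: clean-air prevalence-reduction fractions
#' by venue and level, cessation-treatment effects, health-warning and
#' advertising-ban effects by intensity with enforcement/publicity add-ons,
#' and age-banded price elasticities of demand.
#'
#' @param path YAML file; defaults to the table shipped in `extdata`.
#' @return object of class `policy_effect_table`.
#' @export
default_policy_effects <- function(path = system.file("extdata", "policy_effects.yaml",
                                                      package = "endgamesim")) {
  tab <- yaml::read_yaml(path)
  validate_policy_effects(tab)
}

validate_policy_effects <- function(tab) {
  fr <- c(unlist(tab$clean_air), tab$cessation_treatment$prevalence_reduction,
          unlist(tab$warnings$high), unlist(tab$warnings$low),
          tab$warnings$enforcement_publicity,
          unlist(tab$ad_ban$comprehensive), unlist(tab$ad_ban$complete),
          unlist(tab$ad_ban$partial), tab$ad_ban$enforcement_publicity)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr >= 1)) {
    stop_validation("policy effect fractions must lie in [0, 1)")
  }
  el <- unlist(tab$price_elasticity)
  if (length(el) != 4L || any(el > 0)) stop_validation("price elasticities must be <= 0")
  if (any(diff(abs(el)) > 0)) {
    stop_validation("price-elasticity magnitude must be non-increasing with age band")
  }
  structure(tab, class = "policy_effect_table")
}

#' Describe a policy state
#'
#' Policy levels in force in one calendar year: clean-air laws (P), cessation
#' support (O), health warnings (W) and advertising bans (E), plus
#' enforcement/publicity flags for W and E.
#'
#' @param clean_air `"none"`, `"partial"` or `"complete"`.
#' @param cessation `"none"`, `"partial"` or `"full"`.
#' @param warnings `"low"` or `"high"`.
#' @param warnings_enforced logical: enforcement and publicity both in place
#'   for W (each adds its tabled 1% to every channel).
#' @param ad_ban `"none"`, `"partial"`, `"complete"` or `"comprehensive"`.
#' @param ad_ban_enforced logical: enforcement and publicity both in place
#'   for E (each adds its tabled 1% to every channel).
#' @return object of class `policy_state`.
#' @export
policy_state <- function(clean_air = c("none", "partial", "complete"),
                         cessation = c("none", "partial", "full"),
                         warnings = c("low", "high"),
                         warnings_enforced = FALSE,
                         ad_ban = c("none", "partial", "complete", "comprehensive"),
                         ad_ban_enforced = FALSE) {
  structure(list(clean_air = match.arg(clean_air),
                 cessation = match.arg(cessation),
                 warnings = match.arg(warnings),
                 warnings_enforced = isTRUE(warnings_enforced),
                 ad_ban = match.arg(ad_ban),
                 ad_ban_enforced = isTRUE(ad_ban_enforced)),
            class = "policy_state")
}

# Effect fractions (prevalence, initiation, cessation) of one component at
# one level. Venue-level clean-air effects combine multiplicatively.
component_effects <- function(state, component, table) {
  ca <- table$clean_air
  switch(component,
    P = {
      pe <- switch(state$clean_air,
        none = 0,
        partial = 1 - (1 - ca$workplace_partial) * (1 - ca$restaurant_partial),
        complete = 1 - (1 - ca$workplace_complete) * (1 - ca$restaurant_complete) *
          (1 - ca$bars_other))
      c(prevalence = pe, initiation = pe, cessation = pe)
    },
    O = {
      ct <- table$cessation_treatment
      f <- switch(state$cessation, none = 0, partial = ct$partial_fraction, full = 1)
      c(prevalence = f * ct$prevalence_reduction, initiation = 0,
        cessation = f * ct$cessation_rate_increase)
    },
    W = {
      w <- table$warnings[[state$warnings]]
      add <- if (state$warnings_enforced) 2 * table$warnings$enforcement_publicity else 0
      c(prevalence = w$prevalence + add, initiation = w$initiation + add,
        cessation = w$cessation + add)
    },
    E = {
      if (state$ad_ban == "none") {
        c(prevalence = 0, initiation = 0, cessation = 0)
      } else {
        e <- table$ad_ban[[state$ad_ban]]
        add <- if (state$ad_ban_enforced) 2 * table$ad_ban$enforcement_publicity else 0
        c(prevalence = e$prevalence + add, initiation = e$initiation + add,
          cessation = e$cessation + add)
      }
    },
    stop_validation("unknown policy component: ", component)
  )
}

#' Multipliers implied by a policy-level change
#'
#' For each non-price component the achieved effect fractions are computed at
#' the old and new levels; the prevalence multiplier is the product over
#' components of `(1 - PE_new) / (1 - PE_old)`, the initiation multiplier
#' likewise from initiation effects, and the cessation multiplier is the
#' product of `(1 + CE_new) / (1 + CE_old)`. Identical states give 1.0
#' everywhere, and chained changes compose (A -> B -> C equals A -> C).
#'
#' @param old,new `policy_state` objects.
#' @param table a `policy_effect_table`.
#' @return list with scalar `prevalence`, `initiation`, `cessation`
#'   multipliers (all positive; < 1 means the policy lowers smoking).
#' @export
level_change_multipliers <- function(old, new, table = default_policy_effects()) {
  prev <- init <- cess <- 1
  for (comp in c("P", "O", "W", "E")) {
    eo <- component_effects(old, comp, table)
    en <- component_effects(new, comp, table)
    if (any(c(eo[1:2], en[1:2]) >= 1)) stop_validation("effect fraction >= 1")
    prev <- prev * (1 - en[["prevalence"]]) / (1 - eo[["prevalence"]])
    init <- init * (1 - en[["initiation"]]) / (1 - eo[["initiation"]])
    cess <- cess * (1 + en[["cessation"]]) / (1 + eo[["cessation"]])
  }
  list(prevalence = prev, initiation = init, cessation = cess)
}

#' Deflate a nominal price
#'
#' @param nominal nominal price (KRW per pack).
#' @param base_year year whose prices define the real scale.
#' @param target_year year the nominal price belongs to.
#' @param inflation_rate annual inflation (fraction, default 0.03).
#' @return real price: `nominal / (1 + inflation)^(target_year - base_year)`.
#' @export
deflate <- function(nominal, base_year, target_year, inflation_rate = 0.03) {
  if (any(nominal <= 0)) stop_validation("price must be positive")
  nominal / (1 + inflation_rate)^(target_year - base_year)
}

#' Age-banded price elasticities as a by-age vector
#'
#' Bands: 15--17, 18--24, 25--34, >= 35. Ages below 15 inherit the youngest
#' band (inert in practice: they neither smoke nor initiate).
#'
#' @param table a `policy_effect_table`.
#' @return numeric vector over ages 0--85.
#' @export
price_elasticity_by_age <- function(table = default_policy_effects()) {
  el <- table$price_elasticity
  ages <- model_ages()
  out <- numeric(86)
  out[ages <= 17] <- el$age_15_17
  out[ages >= 18 & ages <= 24] <- el$age_18_24
  out[ages >= 25 & ages <= 34] <- el$age_25_34
  out[ages >= 35] <- el$age_35_plus
  out
}

#' Multipliers implied by a real price change
#'
#' For each age `a`,
#' `prevalence_mult(a) = max(floor, 1 + elasticity(a) * (P_new - P_old) / P_old)`;
#' the same factor applies to initiation, and the cessation multiplier is its
#' reciprocal (bounded above). The scenario engine recomputes these every
#' year from consecutive real (CPI-deflated) prices, so a sustained real
#' increase acts once on the prevalence stock and then persists through the
#' carried stock, and erosion by inflation under a frozen nominal price is
#' automatic.
#'
#' @param price_old_real,price_new_real real prices (> 0).
#' @param table a `policy_effect_table`.
#' @param floor lower bound on the prevalence/initiation multipliers (keeps
#'   probabilities valid under extreme price paths).
#' @param cess_cap upper bound on the cessation multiplier.
#' @return list of numeric vectors over ages 0--85: `prevalence`,
#'   `initiation`, `cessation`.
#' @export
price_multipliers <- function(price_old_real, price_new_real,
                              table = default_policy_effects(),
                              floor = 0.2, cess_cap = 5) {
  if (price_old_real <= 0 || price_new_real <= 0) stop_validation("price must be positive")
  eps <- price_elasticity_by_age(table)
  rel <- (price_new_real - price_old_real) / price_old_real
  pm <- clamp(1 + eps * rel, lo = floor)
  list(prevalence = pm, initiation = pm, cessation = clamp(1 / pm, hi = cess_cap))
}
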