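# Policy-effect arithmetic: level-change and price multipliers, deflation.

test_that("identical policy states give unit multipliers", {
  tab <- default_policy_effects()
  m <- level_change_multipliers(korea_policy_2022(), korea_policy_2022(), tab)
  expect_equal(unlist(m), c(prevalence = 1, initiation = 1, cessation = 1))
})

test_that("level-change multipliers match direct arithmetic from the effect table", {
  tab <- default_policy_effects()
  none <- policy_state("none", "none", "low", FALSE, "none", FALSE)
  # clean air none -> complete: venues combine multiplicatively
  to_p <- policy_state("complete", "none", "low", FALSE, "none", FALSE)
  m <- level_change_multipliers(none, to_p, tab)
  expect_equal(m$prevalence, (1 - 0.06) * (1 - 0.01) * (1 - 0.005), tolerance = 1e-12)
  # ad ban partial -> comprehensive (no enforcement): initiation 8% vs 1%
  from_e <- policy_state("none", "none", "low", FALSE, "partial", FALSE)
  to_e <- policy_state("none", "none", "low", FALSE, "comprehensive", FALSE)
  m2 <- level_change_multipliers(from_e, to_e, tab)
  expect_equal(m2$initiation, (1 - 0.08) / (1 - 0.01), tolerance = 1e-12)
  expect_equal(m2$prevalence, (1 - 0.06) / (1 - 0.01), tolerance = 1e-12)
  # cessation-treatment none -> full raises the quit rate by 50%
  to_o <- policy_state("none", "full", "low", FALSE, "none", FALSE)
  m3 <- level_change_multipliers(none, to_o, tab)
  expect_equal(m3$cessation, 1.5, tolerance = 1e-12)
  expect_equal(m3$prevalence, 1 - 0.026, tolerance = 1e-12)
})

test_that("level changes compose path-independently", {
  tab <- default_policy_effects()
  a <- korea_policy_2022()
  b <- policy_state("complete", "full", "high", FALSE, "partial", FALSE)
  c_ <- full_policy_powe()
  ab <- level_change_multipliers(a, b, tab)
  bc <- level_change_multipliers(b, c_, tab)
  ac <- level_change_multipliers(a, c_, tab)
  for (ch in c("prevalence", "initiation", "cessation")) {
    expect_equal(ab[[ch]] * bc[[ch]], ac[[ch]], tolerance = 1e-12)
  }
})

test_that("stronger policy levels never raise the prevalence multiplier", {
  tab <- default_policy_effects()
  none <- policy_state("none", "none", "low", FALSE, "none", FALSE)
  lvl <- function(p) level_change_multipliers(none, p, tab)$prevalence
  p_seq <- c(lvl(policy_state("none", "none", "low", FALSE, "none", FALSE)),
             lvl(policy_state("partial", "none", "low", FALSE, "none", FALSE)),
             lvl(policy_state("complete", "none", "low", FALSE, "none", FALSE)))
  e_seq <- c(lvl(policy_state("none", "none", "low", FALSE, "none", FALSE)),
             lvl(policy_state("none", "none", "low", FALSE, "partial", FALSE)),
             lvl(policy_state("none", "none", "low", FALSE, "complete", FALSE)),
             lvl(policy_state("none", "none", "low", FALSE, "comprehensive", FALSE)))
  expect_true(all(diff(p_seq) < 0))
  expect_true(all(diff(e_seq) < 0))
})

test_that("price multipliers follow the elasticity equation", {
  tab <- default_policy_effects()
  # no real price change
  m0 <- price_multipliers(4500, 4500, tab)
  expect_equal(m0$prevalence, rep(1, 86))
  expect_equal(m0$cessation, rep(1, 86))
  # KRW 4500 -> 8000, age >= 35 (elasticity -0.1)
  m <- price_multipliers(4500, 8000, tab)
  expect_equal(m$prevalence[40 + 1], 1 - 0.1 * 3500 / 4500, tolerance = 1e-12)
  expect_equal(m$prevalence[16 + 1], 1 - 0.4 * 3500 / 4500, tolerance = 1e-12)
  expect_equal(m$initiation, m$prevalence)
  expect_equal(m$cessation, 1 / m$prevalence)
  # frozen nominal price, 3% inflation: real price falls ~2.91%, youth
  # prevalence multiplier drifts up to ~1.0117
  real_next <- deflate(4500, 2022, 2023)
  md <- price_multipliers(4500, real_next, tab)
  expect_equal(md$prevalence[16 + 1], 1 + (-0.4) * (1 / 1.03 - 1), tolerance = 1e-12)
  expect_equal(round(md$prevalence[16 + 1], 4), 1.0117)
  expect_error(price_multipliers(0, 100, tab), "positive")
})

test_that("the multiplier floor binds under extreme price surges", {
  tab <- default_policy_effects()
  m <- price_multipliers(4500, 45000, tab)   # tenfold real increase
  expect_equal(min(m$prevalence), 0.2)
  expect_true(all(m$cessation <= 5))
})

test_that("raise-then-restore price multipliers cancel to first order", {
  tab <- default_policy_effects()
  up <- price_multipliers(4500, 4545, tab)    # +1% real
  down <- price_multipliers(4545, 4500, tab)
  expect_equal(up$prevalence * down$prevalence, rep(1, 86), tolerance = 1e-3)
})

test_that("deflation follows compound inflation", {
  expect_equal(deflate(8000, 2023, 2023), 8000)
  expect_equal(deflate(8000, 2023, 2024), 7766.99, tolerance = 1e-6)
  expect_equal(deflate(1000, 2020, 2030), 1000 / 1.03^10)
  expect_equal(round(1.03^10, 4), 1.3439)
})

test_that("the shipped effect table carries the published values and validates", {
  tab <- default_policy_effects()
  expect_equal(tab$clean_air$workplace_complete, 0.06)
  expect_equal(tab$cessation_treatment$cessation_rate_increase, 0.5)
  expect_equal(unname(unlist(tab$price_elasticity)), c(-0.4, -0.3, -0.2, -0.1))
  eps <- price_elasticity_by_age(tab)
  expect_equal(eps[17 + 1], -0.4); expect_equal(eps[18 + 1], -0.3)
  expect_equal(eps[34 + 1], -0.2); expect_equal(eps[35 + 1], -0.1)
  expect_true(all(diff(abs(eps)) <= 0))
  bad <- unclass(tab); bad$clean_air$workplace_complete <- 1.2
  expect_error(endgamesim:::validate_policy_effects(bad), "\\[0, 1\\)")
})
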