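# Scenario construction, TFG shutoff, projection properties.

test_that("scenario construction recognizes the seven scenarios", {
  sq <- build_scenario("status_quo")
  expect_length(sq$policy_schedule, 0)
  expect_identical(sq$price_rule$type, "status_quo_nominal")
  expect_null(sq$tfg_cutoff_birth_year)

  full <- build_scenario("POWE+TFG+R8000+R10%")
  expect_identical(endgamesim:::state_in_year(full, 2030), full_policy_powe())
  expect_identical(full$price_rule$type, "jump_growth")
  expect_identical(full$tfg_cutoff_birth_year, 2003L)
  expect_error(build_scenario("ban everything"), "unknown scenario")
})

test_that("price paths implement the jump and growth rules", {
  pp <- price_path(build_scenario("status_quo"))
  expect_true(all(pp$nominal == 4500))
  expect_true(all(diff(pp$real) < 0))   # inflation erodes a frozen price
  pj <- price_path(build_scenario("POWE+R8000"), 2022:2025)
  expect_equal(pj$nominal, c(4500, 8000, 8000, 8000))
  pg <- price_path(build_scenario("POWE+TFG+R8000+R10%"), 2022:2025)
  expect_equal(pg$nominal, c(4500, 8000, 8000 * 1.1, 8000 * 1.1^2))
  expect_equal(pg$real, pg$nominal / 1.03^(0:3))
})

test_that("TFG zeroes initiation exactly for post-cutoff birth cohorts", {
  rates <- zero_rates(initiation = 0.05)
  # 2023, cutoff 2003: born after 2003 means age <= 19
  r23 <- apply_tfg(rates, 2023, 2003)
  expect_true(all(r23$initiation[1:20, ] == 0))
  expect_equal(r23$initiation[21, ], rates$initiation[21, ])  # age 20 untouched
  # 2050: the banned generation has aged to 46
  r50 <- apply_tfg(rates, 2050, 2003)
  expect_true(all(r50$initiation[1:47, ] == 0))
  # absent cutoff is the identity
  expect_identical(apply_tfg(rates, 2030, NULL), rates)
})

test_that("no banned cohort ever initiates during a TFG projection", {
  ser <- cached_series("POWE+TFG")
  gend <- attr(ser, "final_grid")
  expect_identical(gend$year, 2050L)
  # cohorts born 2008+ (aged <= 14 in 2022) start smoke-free and are banned
  # throughout, so they must still be entirely never-smokers at age <= 42
  expect_equal(sum(gend$counts[1:43, , 2:7]), 0)
})

test_that("a zero-effect policy table reduces the scenario engine to raw dynamics", {
  bl <- make_synthetic_baseline()
  ser <- run_scenario(bl, build_scenario("POWE+TFG+R8000+R10%"),
                      effects = zero_effect_table())
  raw <- project_raw(bl$grid, bl$demo, bl$rates, 28)
  # TFG still bites (it is a sales ban, not an effect size), so compare the
  # pure status quo instead for exact equality
  ser_sq <- run_scenario(bl, build_scenario("status_quo"),
                         effects = zero_effect_table())
  expect_equal(ser_sq$male, raw$male, tolerance = 1e-12)
  expect_equal(ser_sq$female, raw$female, tolerance = 1e-12)
  # and the TFG-only variant can only lower prevalence
  expect_true(all(ser$male <= ser_sq$male + 1e-12))
})

test_that("identical inputs give bit-identical projections", {
  bl <- make_synthetic_baseline()
  s1 <- run_scenario(bl, build_scenario("POWE+TFG+R8000+R10%"))
  s2 <- run_scenario(bl, build_scenario("POWE+TFG+R8000+R10%"))
  expect_identical(s1$male, s2$male)
  expect_identical(s1$total, s2$total)
})

test_that("stronger scenario combinations never project higher prevalence", {
  chain_tfg <- c("status_quo", "POWE", "POWE+TFG", "POWE+TFG+R8000",
                 "POWE+TFG+R8000+R10%")
  chain_price <- c("status_quo", "POWE", "POWE+R8000", "POWE+R8000+R10%")
  for (chain in list(chain_tfg, chain_price)) {
    series <- lapply(chain, cached_series)
    for (i in seq_len(length(series) - 1)) {
      for (col in c("male", "female", "total")) {
        expect_true(all(series[[i + 1]][[col]] <= series[[i]][[col]] + 1e-9),
                    info = sprintf("%s vs %s (%s)", chain[i + 1], chain[i], col))
      }
    }
  }
})

test_that("combined totals lie between the sex-specific prevalences", {
  for (nm in scenario_names()) {
    ser <- cached_series(nm)
    expect_true(all(ser$total <= pmax(ser$male, ser$female) + 1e-12))
    expect_true(all(ser$total >= pmin(ser$male, ser$female) - 1e-12))
    expect_true(all(ser$total >= 0 & ser$total <= 100))
  }
})

test_that("scenario deltas difference two projections at a year", {
  a <- cached_series("status_quo")
  expect_equal(scenario_delta(a, a, 2035, "male"), 0)
  b <- cached_series("POWE")
  expect_gt(scenario_delta(a, b, 2030, "male"), 0)
  expect_error(scenario_delta(a, b, 2060, "male"), "outside")
})

test_that("a mismatched baseline year is rejected", {
  bl <- make_synthetic_baseline(year = 2020)
  expect_error(run_scenario(bl, build_scenario("POWE")), "base year")
})
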