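# Markov engine: demography, smoking transitions, prevalence accounting.

test_that("zero mortality and fertility shift every cohort one age and conserve totals", {
  set.seed(42)
  cn <- array(runif(86 * 2 * 7), dim = c(86, 2, 7))
  cn[1:15, , 2:7] <- 0
  g <- population_grid(2022, cn)
  g2 <- evolve_population(g, zero_demo())
  expect_identical(g2$year, 2023L)
  expect_equal(sum(g2$counts), sum(g$counts))
  # cohorts below the terminal bin move up one age
  expect_equal(unname(g2$counts[3:85, , ]), unname(g$counts[2:84, , ]))
  # 85+ absorbs age 84 and itself
  expect_equal(g2$counts[86, , ], g$counts[85, , ] + g$counts[86, , ])
  expect_equal(sum(g2$counts[1, , ]), 0)
})

test_that("certain death with no births empties the population", {
  g <- grid_with(2022, list(list(30, 1, 2, 100), list(70, 2, 1, 50)))
  g2 <- evolve_population(g, zero_demo(mortality = 1))
  expect_equal(sum(g2$counts), 0)
})

test_that("two-age toy population evolves to the hand-computed grid", {
  # ages 0 and 1, 50 male + 50 female each; flat mortality 0.1; fertility 0.5
  # at maternal age 1; sex ratio at birth 0.5.
  # Survivors: 45 per (age, sex). Post-survival females at start-of-year age 1
  # bear 45 * 0.5 = 22.5 births -> 11.25 per sex at age 0.
  g <- grid_with(2022, list(list(0, 1, 1, 50), list(0, 2, 1, 50),
                            list(1, 1, 1, 50), list(1, 2, 1, 50)))
  g2 <- evolve_population(g, zero_demo(mortality = 0.1, fertility_age1 = 0.5))
  expect_equal(g2$counts[1, 1, 1], 11.25)
  expect_equal(g2$counts[1, 2, 1], 11.25)
  expect_equal(unname(g2$counts[2, , 1]), c(45, 45))
  expect_equal(unname(g2$counts[3, , 1]), c(45, 45))
  expect_equal(sum(g2$counts), 202.5)
})

test_that("differential smoker mortality removes more current smokers", {
  g <- grid_with(2022, list(list(40, 1, 1, 100), list(40, 1, 2, 100)))
  demo <- zero_demo(mortality = 0.1)
  demo$mortality_multiplier[2] <- 2   # current smokers die at twice the rate
  g2 <- evolve_population(g, demo)
  expect_equal(g2$counts[42, 1, 1], 90)
  expect_equal(g2$counts[42, 1, 2], 80)
})

test_that("all-zero transition rates change nothing except quit-duration aging", {
  set.seed(1)
  cn <- array(runif(86 * 2 * 7), dim = c(86, 2, 7))
  g <- population_grid(2022, cn)
  g2 <- apply_smoking_transitions(g, zero_rates())
  # never and current stocks are untouched, former mass is conserved, but
  # time since quitting still advances one category (>= 16 y absorbing)
  expect_equal(g2$counts[, , 1:2], g$counts[, , 1:2])
  expect_equal(apply(g2$counts[, , 3:7], c(1, 2), sum),
               apply(g$counts[, , 3:7], c(1, 2), sum))
  expect_equal(unname(g2$counts[, , 4]), unname(g$counts[, , 3]))
  expect_equal(unname(g2$counts[, , 7]), unname(g$counts[, , 6] + g$counts[, , 7]))
  expect_true(all(g2$counts[, , 3] == 0))
})

test_that("initiation moves the expected fraction of never smokers", {
  g <- grid_with(2022, list(list(20, 1, 1, 1000)))
  g2 <- apply_smoking_transitions(g, zero_rates(initiation = 0.1))
  expect_equal(g2$counts[21, 1, 1], 900)
  expect_equal(g2$counts[21, 1, 2], 100)
})

test_that("cessation and relapse flows match the hand-expanded update", {
  # 500 current (cessation 0.2) and 200 in the 1-2y former category
  # (relapse 0.3): 100 quit, 60 relapse, 140 advance one duration category.
  g <- grid_with(2022, list(list(40, 1, 2, 500), list(40, 1, 3, 200)))
  g2 <- apply_smoking_transitions(g, zero_rates(cessation = 0.2, relapse1 = 0.3))
  expect_equal(g2$counts[41, 1, 2], 500 - 100 + 60)
  expect_equal(g2$counts[41, 1, 3], 100)
  expect_equal(g2$counts[41, 1, 4], 140)
  expect_equal(sum(g2$counts), 700)   # transitions conserve people
})

test_that("smoking transitions conserve every cohort total", {
  set.seed(99)
  for (rep in 1:5) {
    cn <- array(rexp(86 * 2 * 7), dim = c(86, 2, 7))
    g <- population_grid(2022, cn)
    rates <- zero_rates(initiation = runif(1), cessation = runif(1),
                        relapse1 = runif(1))
    g2 <- apply_smoking_transitions(g, rates)
    expect_equal(apply(g2$counts, c(1, 2), sum), apply(g$counts, c(1, 2), sum),
                 tolerance = 1e-12)
    expect_true(all(g2$counts >= 0))
  }
})

test_that("adult prevalence handles the edge and reference cases", {
  g <- grid_with(2022, list(list(30, 1, 1, 1000)))
  expect_equal(adult_prevalence(g, sex = "male"), 0)
  g_all <- grid_with(2022, list(list(30, 1, 2, 1000)))
  expect_equal(adult_prevalence(g_all, sex = "male"), 100)
  # 353 current of 1000 adult males: the published 2022 male starting point
  g_mix <- grid_with(2022, list(list(30, 1, 2, 353), list(30, 1, 1, 647)))
  expect_equal(adult_prevalence(g_mix, sex = "male"), 35.3)
  expect_error(adult_prevalence(g_mix, sex = "female"), "no population")
})

test_that("invalid inputs are rejected", {
  cn <- array(0, dim = c(86, 2, 7)); cn[1] <- -1
  expect_error(population_grid(2022, cn), "non-negative")
  expect_error(demographic_rates(rep(-1, 86), matrix(0, 86, 2)), "non-negative")
  expect_error(demographic_rates(numeric(86), matrix(2, 86, 2)), "\\[0, 1\\]")
  init_bad <- matrix(0, 86, 2); init_bad[5, 1] <- 0.1  # initiation at age 4
  expect_error(transition_rates(init_bad, matrix(0, 86, 2), matrix(0, 5, 2)),
               "initiation window")
  rel_bad <- matrix(c(0.1, 0.2, 0.1, 0.1, 0.1), 5, 2)
  expect_error(transition_rates(matrix(0, 86, 2), matrix(0, 86, 2), rel_bad),
               "non-increasing")
})

test_that("never-smoker fraction follows the closed form under constant initiation", {
  # single cohort entering the initiation window: after 5 years at i = 0.05,
  # never fraction is 0.95^5 exactly and prevalence is 1 - 0.95^5 = 0.2262.
  g <- grid_with(2022, list(list(18, 1, 1, 1000)))
  rates <- zero_rates(initiation = 0.05)
  out <- project_raw(g, zero_demo(), rates, 5)
  gk <- g
  for (k in 1:5) {
    gk <- evolve_population(gk, zero_demo())
    gk <- apply_smoking_transitions(gk, rates)
  }
  expect_equal(gk$counts[24, 1, 1], 1000 * 0.95^5)
  expect_equal(out$male[6], 100 * (1 - 0.95^5), tolerance = 1e-12)
})
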