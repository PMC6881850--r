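test_that("annual_state_cost prices occupancy by age group and state", {
  cohorts <- empty_cohorts()
  cohorts["adults.seasonal.ST", "A"] <- 100
  expect_equal(annual_state_cost(cohorts), 800)

  healthy <- empty_cohorts()
  healthy[, "E"] <- 50
  expect_equal(annual_state_cost(healthy), 0)

  set.seed(15)
  cohorts <- random_cohorts()
  costs <- cost_table()
  # brute-force loop oracle
  expected <- 0
  parts <- split_stratum_id(rownames(cohorts))
  for (i in seq_len(nrow(cohorts))) for (s in diseased_states())
    expected <- expected + cohorts[i, s] * costs[parts$group[i], s]
  expect_equal(annual_state_cost(cohorts, costs), expected, tolerance = 1e-9)
})

test_that("scit_mean_cost averages the preseasonal and perennial prices", {
  sched <- scit_cost_schedule()
  expect_identical(scit_mean_cost(sched, 1), 382)
  expect_identical(scit_mean_cost(sched, 2), 371)
  expect_identical(scit_mean_cost(sched, 3), 371)

  flat <- scit_cost_schedule(preseasonal = rep(300, 3), perennial = rep(300, 3))
  expect_equal(scit_mean_cost(flat, 2), 300)

  expect_error(scit_mean_cost(sched, 4), "therapy_year")
})

test_that("discounting follows the closed form and decreases in the rate", {
  spec <- discount_spec(rate = 0.02, base_year = 2011)
  expect_equal(discount(100, 2011, spec), 100)
  expect_equal(discount(102, 2012, spec), 100)
  expect_equal(discount(100, 2050, spec), 100 / 1.02^39)

  # strictly decreasing in the rate for a cost stream after the base year
  stream <- stats::runif(10, 100, 1000)
  years <- 2012:2021
  totals <- vapply(c(0.00, 0.01, 0.02, 0.05, 0.10), function(r)
    sum(discount(stream, years, discount_spec(rate = r, base_year = 2011))),
    numeric(1))
  expect_true(all(diff(totals) < 0))

  expect_error(discount(100, 2010, spec), "before the base year")
  expect_error(discount_spec(rate = 0.2), "\\[0, 0.10\\]")
})

test_that("run_scenario on empty inputs yields an all-zero result", {
  params <- make_fixture_config("toy", seed = 1)
  params$prevalence <- prevalence_table(
    ar = c(children = 0, adolescents = 0, adults = 0),
    aa = c(children = 0, adolescents = 0, adults = 0))
  res <- run_scenario(builtin_scenarios()$status_quo, params,
                      incidence = zero_incidence(params$horizon))
  expect_equal(sum(res$occupancy), 0)
  expect_equal(sum(res$by_year$total_cost), 0)
})

test_that("run_scenario accounts costs exactly and is deterministic", {
  params <- make_fixture_config("toy", seed = 1)
  res <- run_scenario(builtin_scenarios()$status_quo, params)
  yr <- res$by_year
  expect_equal(yr$total_cost, yr$state_cost + yr$scit_cost)
  expect_equal(yr$total_cost_discounted,
               discount(yr$total_cost, yr$year, params$discount))
  expect_true(all(yr$total_cost_discounted <= yr$total_cost + 1e-12))

  again <- run_scenario(builtin_scenarios()$status_quo, params)
  expect_identical(res$by_year, again$by_year)
  expect_identical(res$occupancy, again$occupancy)
})

test_that("the toy trajectory matches hand-computed matrix products", {
  params <- make_fixture_config("toy", seed = 1)
  res <- run_scenario(null_scenario(), params,
                      incidence = zero_incidence(params$horizon))
  m_child <- params$matrices[["children.seasonal.ST"]]
  m_adol <- params$matrices[["adolescents.seasonal.ST"]]
  v0 <- res$occupancy["2011", "children.seasonal.ST", ]
  # year 2012: advance under the children matrix, then 1/7 ages up
  v1 <- drop(v0 %*% m_child)
  expect_equal(res$occupancy["2012", "children.seasonal.ST", ], v1 * 6 / 7)
  expect_equal(res$occupancy["2012", "adolescents.seasonal.ST", ], v1 / 7)
  # year 2013, children stratum: only the remaining children advance and age
  v2c <- drop((v1 * 6 / 7) %*% m_child) * 6 / 7
  expect_equal(res$occupancy["2013", "children.seasonal.ST", ], v2c)
  # year 2013, adolescents: last year's inflow advances under the adolescent
  # matrix, loses 1/6 upward, and gains the children inflow
  v2a <- drop((v1 / 7) %*% m_adol) * 5 / 6 + drop((v1 * 6 / 7) %*% m_child) / 7
  expect_equal(res$occupancy["2013", "adolescents.seasonal.ST", ], v2a)
})

test_that("icer reproduces the published comparison arithmetic", {
  expect_identical(icer(98964793, 288213), 343)
  expect_identical(icer(131341777, 424559), 309)
  expect_identical(icer(-1250059, 32794), "dominant")
  expect_identical(icer(-5732459, 67126), "dominant")

  # homogeneity: scaling cost and effect together leaves the ratio unchanged
  for (k in c(0.5, 2, 10)) {
    expect_identical(icer(98964793 * k, 288213 * k), 343)
  }
  expect_error(icer(100, 0), "strictly positive")
  expect_error(icer(100, -5), "strictly positive")
})

test_that("compare_to_status_quo recovers injected differences exactly", {
  params <- make_fixture_config("toy", seed = 1)
  base <- run_scenario(builtin_scenarios()$status_quo, params)

  shifted <- base
  shifted$scenario <- "shifted"
  shifted$by_year$total_cost_discounted <- base$by_year$total_cost_discounted + 1000
  shifted$by_year$healed_total <- base$by_year$healed_total + 4

  cmp <- compare_to_status_quo(list(status_quo = base, shifted = shifted))
  expect_equal(cmp$delta_mean_annual_cost, 1000)
  expect_equal(cmp$delta_mean_annual_healed, 4)
  expect_equal(cmp$icer, 250)

  same <- compare_to_status_quo(list(status_quo = base, twin = base))
  expect_equal(same$delta_mean_annual_cost, 0)
  expect_equal(same$delta_mean_annual_healed, 0)
  expect_identical(same$icer_label, "undefined")

  expect_error(compare_to_status_quo(list(a = base)), "missing from results")
})
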