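test_that("the built-in scenarios carry the published schedules and eligibility", {
  sc <- builtin_scenarios()
  expect_named(sc, c("status_quo", "scenario_1", "scenario_2",
                     "scenario_3", "scenario_4"))

  sq <- sc$status_quo
  expect_equal(sq$eligible_states, c("C", "D"))
  expect_equal(sq$schedule$rate_start["adults", "seasonal"], 0.20)
  expect_equal(sq$schedule$rate_start["children", "seasonal"], 0.05)
  expect_equal(sq$schedule$rate_start["adolescents", "perennial"], 0.10)
  expect_equal(sq$schedule$rate_target["children", "seasonal"], 0.10)
  expect_equal(sq$schedule$rate_target["children", "perennial"], 0.05)
  expect_equal(sq$schedule$rate_target["adults", "perennial"], 0.30)
  expect_equal(sq$schedule$target_year, 2030)

  # tripled 2011 rates by 2020
  expect_equal(sc$scenario_1$schedule$rate_target["adults", "seasonal"], 0.60)
  expect_equal(sc$scenario_1$schedule$rate_target,
               3 * sc$scenario_1$schedule$rate_start)
  expect_equal(sc$scenario_1$schedule$target_year, 2020)

  # 75% everywhere by 2020
  expect_true(all(sc$scenario_2$schedule$rate_target == 0.75))

  # widened therapy-onset eligibility, same schedule as status quo
  expect_equal(sc$scenario_3$eligible_states, c("B", "C", "D"))
  expect_equal(sc$scenario_4$eligible_states, c("A", "B", "C", "D"))
  expect_equal(sc$scenario_3$schedule, sq$schedule)
  expect_equal(sc$scenario_4$schedule, sq$schedule)
})

test_that("supply_rate interpolates linearly and is constant after the target year", {
  sq <- builtin_scenarios()$status_quo$schedule
  expect_equal(supply_rate(sq, "adults", "seasonal", 2011), 0.20)
  expect_equal(supply_rate(sq, "adults", "seasonal", 2030), 0.30)
  expect_equal(supply_rate(sq, "adults", "seasonal", 2040), 0.30)

  s1 <- builtin_scenarios()$scenario_1$schedule
  expect_equal(supply_rate(s1, "children", "seasonal", 2016),
               0.05 + (0.15 - 0.05) * 5 / 9)

  # non-decreasing in year when the target exceeds the start rate
  years <- 2011:2050
  for (g in age_groups()) for (t in allergy_types()) {
    r <- supply_rate(sq, g, t, years)
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(r >= 0 & r <= 1))
  }

  expect_error(supply_rate(sq, "adults", "seasonal", 2010), "must lie in")
  expect_error(supply_schedule(rate_matrix(0.5), rate_matrix(1.5), 2030),
               "\\[0, 1\\]")
  expect_error(supply_schedule(rate_matrix(0.5), rate_matrix(0.6), 2011),
               "target_year")
})

test_that("allocate_scit moves the supply-rate fraction of eligible ST patients", {
  cohorts <- empty_cohorts()
  cohorts["adults.seasonal.ST", diseased_states()] <- c(10, 20, 30, 40)

  flat <- function(rate, elig) {
    scenario_spec("x", supply_schedule(rate_matrix(rate), rate_matrix(rate), 2050),
                  elig)
  }

  expect_equal(allocate_scit(cohorts, flat(0, c("C", "D")), 2011), cohorts)

  all_cd <- allocate_scit(cohorts, flat(1, c("C", "D")), 2011)
  expect_equal(unname(all_cd["adults.seasonal.SCIT1", c("C", "D")]), c(30, 40))
  expect_equal(unname(all_cd["adults.seasonal.ST", c("C", "D")]), c(0, 0))
  expect_equal(unname(all_cd["adults.seasonal.ST", c("A", "B")]), c(10, 20))

  # hand computation: 30% of (B, C, D) = (6, 9, 12); A untouched
  part <- allocate_scit(cohorts, flat(0.3, c("B", "C", "D")), 2011)
  expect_equal(unname(part["adults.seasonal.SCIT1", diseased_states()]),
               c(0, 6, 9, 12))
  expect_equal(unname(part["adults.seasonal.ST", diseased_states()]),
               c(10, 14, 21, 28))
  expect_equal(sum(part), sum(cohorts))
})

test_that("allocation conserves persons and never touches SCIT or POST arms", {
  set.seed(14)
  for (i in 1:20) {
    cohorts <- random_cohorts()
    rate <- stats::runif(1)
    elig <- sample(diseased_states(), sample(1:4, 1))
    spec <- scenario_spec("x", supply_schedule(rate_matrix(rate),
                                               rate_matrix(rate), 2050), elig)
    out <- allocate_scit(cohorts, spec, 2025)
    expect_equal(sum(out), sum(cohorts), tolerance = 1e-9)
    arm <- split_stratum_id(rownames(cohorts))$arm
    untouched <- arm %in% c("SCIT2", "SCIT3", "POST")
    expect_equal(out[untouched, ], cohorts[untouched, ])
    expect_true(all(out >= 0))
  }
})

test_that("stock allocation tops the SCIT arms up to the target share", {
  cohorts <- empty_cohorts()
  cohorts["adults.seasonal.ST", "C"] <- 60
  cohorts["adults.seasonal.SCIT2", "C"] <- 40
  spec <- scenario_spec("x", supply_schedule(rate_matrix(0.5),
                                             rate_matrix(0.5), 2050), c("C", "D"))
  out <- allocate_scit(cohorts, spec, 2011, allocation = "stock")
  # target 0.5 * 100 = 50 under treatment; 40 already on SCIT -> move 10
  expect_equal(out["adults.seasonal.SCIT1", "C"], 10)
  expect_equal(out["adults.seasonal.ST", "C"], 50)
  # already at target: nothing moves
  again <- allocate_scit(out, spec, 2011, allocation = "stock")
  expect_equal(again, out)
})

test_that("scenario YAML files round-trip and are validated on read", {
  dir <- withr::local_tempdir()
  paths <- export_builtin_scenarios(dir)
  expect_length(paths, 5)
  back <- read_scenario_yaml(file.path(dir, "scenario_3.yaml"))
  expect_equal(back, builtin_scenarios()$scenario_3)

  bad <- file.path(dir, "bad.yaml")
  yaml::write_yaml(list(name = "x"), bad)
  expect_error(read_scenario_yaml(bad), "missing fields")
})
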