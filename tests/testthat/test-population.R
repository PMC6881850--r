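test_that("population_under_risk sums the age-group spans and excludes other ages", {
  proj <- uniform_projection(2011, per_age = 1000)
  expect_equal(population_under_risk(proj, 2011),
               c(children = 7000, adolescents = 6000, adults = 47000))

  empty <- proj
  empty$count[empty$age %in% 6:65] <- 0
  expect_equal(unname(population_under_risk(empty, 2011)), c(0, 0, 0))

  set.seed(12)
  rnd <- proj
  rnd$count <- stats::runif(nrow(rnd), 0, 5000)
  got <- population_under_risk(rnd, 2011)
  # brute-force summation oracle
  for (g in names(age_group_spans())) {
    expect_equal(got[[g]],
                 sum(rnd$count[rnd$age %in% age_group_spans()[[g]]]))
  }

  expect_error(population_under_risk(proj, 2050), "outside the projection range")
})

test_that("projection validation rejects malformed tables and CSV round-trips", {
  proj <- uniform_projection(2011:2012)
  expect_silent(validate_projection(proj))

  expect_error(validate_projection(proj[proj$age != 50, ]),
               "exactly one row per")
  neg <- proj; neg$count[1] <- -1
  expect_error(validate_projection(neg), "non-negative")
  gap <- proj; gap$year[gap$year == 2012] <- 2014
  expect_error(validate_projection(gap), "contiguous")

  path <- withr::local_tempfile(fileext = ".csv")
  write_projection_csv(proj, path)
  expect_equal(read_projection_csv(path)$count, proj$count)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("jahr,alter,n", "2011,0,5"), bad)
  expect_error(read_projection_csv(bad), "header")
})

test_that("the prevalent pool applies prevalence, AA/AR overlap and the seasonal split", {
  # one million children, nobody else
  proj <- uniform_projection(2011, per_age = 0)
  proj$count[proj$age %in% 6:12] <- 1e6 / 7
  prev <- prevalence_table(ar = c(children = 0.047, adolescents = 0, adults = 0),
                           aa = c(children = 0.036, adolescents = 0, adults = 0),
                           seasonal_share = 0.6)
  pool <- initial_prevalent_pool(proj, prev)
  # AA is a subset of AR, so total diseased = AR prevalence count
  expect_equal(diseased_total(pool), 47000, tolerance = 1e-9)
  # AA persons sit in C/D, AR-only in A/B
  totals <- cohort_state_totals(pool)
  expect_equal(unname(totals["C"] + totals["D"]), 36000, tolerance = 1e-9)
  expect_equal(unname(totals["A"] + totals["B"]), 11000, tolerance = 1e-9)
  # seasonal : perennial = 3 : 2 in every occupied stratum
  seas <- pool["children.seasonal.ST", ]
  per <- pool["children.perennial.ST", ]
  expect_equal(seas, per * 1.5, tolerance = 1e-12)
  # everyone starts in the ST arm
  arm <- split_stratum_id(rownames(pool))$arm
  expect_equal(sum(pool[arm != "ST", ]), 0)

  zero <- initial_prevalent_pool(proj, prevalence_table(
    ar = c(children = 0, adolescents = 0, adults = 0),
    aa = c(children = 0, adolescents = 0, adults = 0)))
  expect_equal(sum(zero), 0)
})

test_that("the prevalent pool scales linearly in population and prevalence", {
  proj1 <- uniform_projection(2011, per_age = 1000)
  proj2 <- uniform_projection(2011, per_age = 3000)
  p1 <- initial_prevalent_pool(proj1, prevalence_table())
  p2 <- initial_prevalent_pool(proj2, prevalence_table())
  expect_equal(p2, p1 * 3, tolerance = 1e-12)

  half <- prevalence_table(
    ar = c(children = 0.047, adolescents = 0.169, adults = 0.1795) / 2,
    aa = c(children = 0.036, adolescents = 0.057, adults = 0.039) / 2)
  expect_equal(initial_prevalent_pool(proj1, half), p1 / 2, tolerance = 1e-12)
})

test_that("age_cohorts moves uniform-age fractions up and conserves persons", {
  cohorts <- empty_cohorts()
  cohorts["children.seasonal.ST", "A"] <- 700
  out <- age_cohorts(cohorts)
  expect_equal(out["children.seasonal.ST", "A"], 600)
  expect_equal(out["adolescents.seasonal.ST", "A"], 100)
  expect_equal(sum(attr(out, "outflow")), 0)

  expect_equal(`attr<-`(age_cohorts(empty_cohorts()), "outflow", NULL),
               empty_cohorts())

  set.seed(13)
  cohorts <- random_cohorts()
  out <- age_cohorts(cohorts)
  parts <- split_stratum_id(rownames(cohorts))
  # bookkeeping oracle: per (type, arm, state), adolescent inflow equals
  # children outflow
  for (t in allergy_types()) for (a in treatment_arms()) {
    ch <- stratum_id("children", t, a)
    ad <- stratum_id("adolescents", t, a)
    inflow <- out[ad, ] - cohorts[ad, ] * (1 - 1 / 6)
    expect_equal(inflow, cohorts[ch, ] / 7, tolerance = 1e-9)
  }
  # totals conserved apart from adult outflow
  adult_out <- attr(out, "outflow")
  expect_equal(sum(out) + sum(adult_out), sum(cohorts), tolerance = 1e-8)
  expect_equal(unname(adult_out),
               unname(colSums(cohorts[parts$group == "adults", ]) / 47),
               tolerance = 1e-9)
})

test_that("incidence calibration holds the diseased total on the demographic trend", {
  params <- make_fixture_config("toy", seed = 1)
  sched <- calibrate_incidence(params, tol = 0.005)
  ratio <- attr(sched, "achieved_ratio")
  # constant population: diseased total constant within tolerance
  expect_true(all(abs(ratio - 1) <= 0.005))
  expect_true(all(sched >= 0))
  # entrants confined to the children ST strata
  nonchild <- setdiff(colnames(sched), stratum_id("children", allergy_types(), "ST"))
  expect_equal(sum(sched[, nonchild]), 0)

  expect_error(calibrate_incidence(params, tol = 0), "strictly positive")
})
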