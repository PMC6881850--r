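# Ranges collapsed onto the published point values: sampling them must
# always return the deterministic configuration.
degenerate_ranges <- function() {
  pts <- c(prev_ar_children = 0.047, prev_ar_adolescents = 0.169,
           prev_ar_adults = 0.1795,
           prev_aa_children = 0.036, prev_aa_adolescents = 0.057,
           prev_aa_adults = 0.039,
           seasonal_share = 0.60,
           cost_children_A = 27, cost_children_B = 119,
           cost_children_C = 282, cost_children_D = 446,
           cost_adolescents_A = 18, cost_adolescents_B = 97,
           cost_adolescents_C = 259, cost_adolescents_D = 442,
           cost_adults_A = 8, cost_adults_B = 79,
           cost_adults_C = 227, cost_adults_D = 442,
           scit_cost_year1 = 382, scit_cost_year2 = 371, scit_cost_year3 = 371,
           discount_rate = 0.02, transition_perturbation = 0)
  do.call(parameter_ranges, lapply(pts, function(x) c(x, x)))
}

test_that("sample_parameters draws uniformly within bounds, reproducibly", {
  r <- parameter_ranges()
  d1 <- sample_parameters(r, seed = 99)
  d2 <- sample_parameters(r, seed = 99)
  expect_identical(d1, d2)
  for (nm in names(r)) {
    expect_gte(d1[[nm]], r[[nm]][1])
    expect_lte(d1[[nm]], r[[nm]][2])
  }

  expect_equal(unname(sample_parameters(degenerate_ranges(), seed = 1)["discount_rate"]),
               0.02)

  # uniform-distribution oracle on the discount rate
  set.seed(7)
  draws <- replicate(10000, sample_parameters(r)[["discount_rate"]])
  expect_true(all(draws >= 0.015 & draws <= 0.025))
  se <- (0.01 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.02), 3 * se)

  expect_error(parameter_ranges(discount_rate = c(0.03, 0.01)), "low <= high")
  expect_error(parameter_ranges(nonsense = c(0, 1)), "unknown parameter")
})

test_that("degenerate ranges give zero dispersion and the deterministic mean", {
  params <- make_fixture_config("toy", seed = 1)
  specs <- builtin_scenarios()[c("status_quo", "scenario_4")]
  ps <- run_psa(specs, params, ranges = degenerate_ranges(), n_reps = 5, seed = 3)
  expect_true(all(ps$sd == 0))

  # deterministic reference: the same point parameters applied once
  draws <- sample_parameters(degenerate_ranges(), seed = 1)
  params_pt <- apply_parameters(params, draws)
  res <- run_scenario(specs$status_quo, params_pt)
  yr <- res$by_year
  expect_equal(ps$mean[ps$scenario == "status_quo" & ps$output == "diseased_total"],
               mean(yr$diseased_total))
  expect_equal(ps$mean[ps$scenario == "status_quo" & ps$output == "total_cost"],
               mean(yr$total_cost_discounted))
})

test_that("common random numbers cancel exactly between identical scenarios", {
  params <- make_fixture_config("toy", seed = 1)
  twin <- builtin_scenarios()$status_quo
  twin$name <- "twin"
  ps <- run_psa(list(builtin_scenarios()$status_quo, twin), params,
                n_reps = 4, seed = 5)
  reps <- attr(ps, "replicates")
  expect_equal(reps[, "status_quo", ], reps[, "twin", ], tolerance = 1e-12)
})

test_that("the replicate seed stream is a prefix-stable sequence", {
  params <- make_fixture_config("toy", seed = 1)
  specs <- builtin_scenarios()["status_quo"]
  short <- run_psa(specs, params, n_reps = 3, seed = 11)
  long <- run_psa(specs, params, n_reps = 6, seed = 11)
  expect_equal(attr(long, "samples")[1:3, ], attr(short, "samples"))
  expect_equal(attr(long, "replicates")[1:3, , ],
               attr(short, "replicates")[1:3, , ])
  expect_true(all(is.finite(attr(long, "samples"))))
  expect_error(run_psa(specs, params, n_reps = 1, seed = 1), "at least 2")
})

test_that("widening an input range widens the output dispersion", {
  params <- make_fixture_config("toy", seed = 1)
  specs <- builtin_scenarios()["status_quo"]
  narrow <- degenerate_ranges()
  narrow$cost_children_C <- c(282 - 25, 282 + 25)
  wide <- degenerate_ranges()
  wide$cost_children_C <- c(282 - 100, 282 + 100)
  sd_of <- function(r) {
    ps <- run_psa(specs, params, ranges = r, n_reps = 30, seed = 17)
    ps$sd[ps$output == "total_cost"]
  }
  expect_gte(sd_of(wide), 2 * sd_of(narrow))
})

test_that("sampled transition perturbation keeps matrices valid", {
  params <- make_fixture_config("toy", seed = 1)
  r <- degenerate_ranges()
  r$transition_perturbation <- c(0.05, 0.05)
  draws <- sample_parameters(r, seed = 21)
  perturbed <- apply_parameters(params, draws, matrix_seed = 21)
  expect_silent(validate_transition_set(perturbed$matrices))
  expect_false(identical(perturbed$matrices, params$matrices))
  # reproducible under the same seed
  again <- apply_parameters(params, draws, matrix_seed = 21)
  expect_identical(perturbed$matrices, again$matrices)
})
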