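# Shared fixture builders. Everything is generated in code at test time.

# Random row-stochastic 6x6 matrix with absorbing death, optionally with a
# guaranteed death probability of at least `min_death` in every row.
random_valid_matrix <- function(min_death = 0) {
  m <- matrix(stats::runif(36), 6, 6,
              dimnames = list(disease_states(), disease_states()))
  m <- m / rowSums(m)
  if (min_death > 0) {
    m[, "F"] <- m[, "F"] + min_death
    m <- m / rowSums(m)
  }
  m["F", ] <- c(0, 0, 0, 0, 0, 1)
  m
}

# Random transition set over the 12 (group, type, treatment) keys.
random_transition_set <- function(min_death = 0) {
  set <- lapply(transition_set_keys(), function(k) random_valid_matrix(min_death))
  names(set) <- transition_set_keys()
  set
}

# Random non-negative cohort occupancy over all 30 strata.
random_cohorts <- function(scale = 1000) {
  cohorts <- empty_cohorts()
  cohorts[] <- stats::runif(length(cohorts)) * scale
  cohorts
}

# A projection with a constant count at every age, for hand-checkable sums.
uniform_projection <- function(years = 2011:2013, per_age = 1000) {
  proj <- expand.grid(year = years, age = 0:100)
  proj <- proj[order(proj$year, proj$age), ]
  proj$count <- per_age
  proj
}

# Desk-scale fixture, built once per test run.
desk_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture_config("desk", seed = 1)
    cache
  }
})

# An all-zero incidence schedule for a horizon.
zero_incidence <- function(horizon) incidence_schedule(horizon[-1])
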