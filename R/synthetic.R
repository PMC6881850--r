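# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic population projection
#'
#' Emulates a national 2011-2050 population projection by single age-year,
#' for pipelines whose real demographic input is not redistributable. The
#' population under risk (ages 6-65) follows the requested geometric trend
#' exactly: in year `2011 + k` it equals `base_pop_6_65 * (1 + annual_trend)^k`.
#' The `"youth-declining"` profile additionally shrinks the share of ages
#' 6-18 by 1% per year relative to ages 19-65 (total still on trend),
#' mimicking an ageing population in which the number of young allergy
#' patients falls fastest. A seeded multiplicative perturbation of the age
#' profile (`jitter_sd`) makes the table look less artificial; it is drawn
#' once and reused every year, so a zero trend with the flat profile yields
#' identical counts in every year.
#'
#' @param base_pop_6_65 Persons aged 6-65 in 2011; must be positive.
#' @param annual_trend Yearly geometric growth rate, in \[-0.05, 0.05\].
#' @param age_profile `"flat"` or `"youth-declining"`.
#' @param seed RNG seed for the age-profile jitter.
#' @param jitter_sd Log-normal sd of the per-age jitter (default 0, exact
#'   uniform profile).
#' @return Population projection data frame (`year`, `age`, `count`)
#'   covering 2011-2050 x ages 0-100; passes [validate_projection()].
#' @export
#' @examples
#' proj <- generate_population_projection(6e7, -0.004, "youth-declining", seed = 1)
#' sum(population_under_risk(proj, 2011))
generate_population_projection <- function(base_pop_6_65, annual_trend = 0,
                                           age_profile = c("flat", "youth-declining"),
                                           seed = 1, jitter_sd = 0) {
  age_profile <- match.arg(age_profile)
  if (base_pop_6_65 <= 0) stop("base_pop_6_65 must be positive")
  if (abs(annual_trend) > 0.05) stop("annual_trend must lie in [-0.05, 0.05]")
  years <- 2011:2050
  ages <- 0:100
  w <- rep(1, length(ages))
  if (jitter_sd > 0)
    w <- with_seed(seed, exp(stats::rnorm(length(ages), 0, jitter_sd)))
  risk <- ages >= 6 & ages <= 65
  young <- ages >= 6 & ages <= 18
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    k <- years[i] - 2011
    wy <- w
    if (age_profile == "youth-declining") wy[young] <- wy[young] * 0.99^k
    target <- base_pop_6_65 * (1 + annual_trend)^k
    counts <- numeric(length(ages))
    counts[risk] <- wy[risk] / sum(wy[risk]) * target
    # ages outside 6-65 follow the overall trend at the base per-age level
    counts[!risk] <- wy[!risk] * (base_pop_6_65 / sum(ages >= 6 & ages <= 65)) *
      (1 + annual_trend)^k
    out[[i]] <- data.frame(year = years[i], age = ages, count = counts)
  }
  proj <- do.call(rbind, out)
  validate_projection(proj)
  proj
}

#' Synthetic transition matrices for every stratum
#'
#' The published model's transition probabilities are not in the public
#' record; this generator produces plausible placeholder dynamics, clearly
#' tagged as synthetic, that respect the model's qualitative structure:
#' worsening along `A -> B -> C -> D`, one-step improvement, remission to
#' the healthy state E (including spontaneous healing), a small absorbing
#' death probability in every row, and a small relapse from E. SCIT
#' matrices are derived from the symptomatic-therapy (ST) matrices of the
#' same stratum by scaling remission/improvement up and progression/relapse
#' down with `effect_size`:
#' remission x `(1 + 2 * effect_size)`, improvement x `(1 + effect_size)`,
#' progression and relapse x `(1 - 0.7 * effect_size)`. Consequences:
#' `effect_size = 0` makes SCIT identical to ST, and SCIT remission entries
#' are monotone non-decreasing in `effect_size`.
#'
#' Base yearly rates (ST, before age/type modifiers) — synthetic, chosen as
#' field-plausible magnitudes, not published values:
#' A: worsen 0.10, heal 0.06; B: worsen 0.07, improve 0.05, heal 0.03;
#' C: worsen 0.06, improve 0.04, heal 0.02; D: improve 0.05, heal 0.01;
#' E: relapse 0.01. Children progress and heal slightly faster than adults;
#' perennial disease progresses slightly faster and remits slower than
#' seasonal. Optional seeded jitter (+/-10% uniform, per stratum and rate)
#' varies the base rates; SCIT matrices are derived from the jittered ST
#' rates, so the SCIT-vs-ST contracts hold for any seed.
#'
#' @param effect_size SCIT benefit scale in \[0, 1\].
#' @param seed RNG seed for the jitter, or `NULL` for the unjittered rates.
#' @param jitter If `TRUE` (default when `seed` given), apply the +/-10%
#'   rate jitter.
#' @return Transition set (named list of 12 validated matrices, keys
#'   `"<group>.<type>.<ST|SCIT>"`) with attribute `provenance = "synthetic"`.
#' @export
#' @examples
#' set <- default_transition_params(effect_size = 0.5, seed = 7)
#' set[["adults.seasonal.SCIT"]]["C", "E"] >= set[["adults.seasonal.ST"]]["C", "E"]
default_transition_params <- function(effect_size = 0.5, seed = NULL,
                                      jitter = !is.null(seed)) {
  if (effect_size < 0 || effect_size > 1)
    stop("effect_size must lie in [0, 1]")
  states <- disease_states()
  base_moves <- list(  # from, to, rate, kind
    list("A", "B", 0.10, "worsen"), list("A", "E", 0.06, "heal"),
    list("B", "C", 0.07, "worsen"), list("B", "A", 0.05, "improve"),
    list("B", "E", 0.03, "heal"),
    list("C", "D", 0.06, "worsen"), list("C", "B", 0.04, "improve"),
    list("C", "E", 0.02, "heal"),
    list("D", "C", 0.05, "improve"), list("D", "E", 0.01, "heal"),
    list("E", "A", 0.01, "relapse")
  )
  mort <- c(children = 0.0002, adolescents = 0.0003, adults = 0.002)
  prog_mult <- c(children = 1.1, adolescents = 1.0, adults = 0.9)
  heal_mult <- c(children = 1.2, adolescents = 1.0, adults = 0.8)
  type_prog <- c(seasonal = 1.0, perennial = 1.1)
  type_heal <- c(seasonal = 1.0, perennial = 0.9)

  build <- function(rates, death) {
    m <- matrix(0, 6, 6, dimnames = list(states, states))
    for (mv in rates) m[mv$from, mv$to] <- m[mv$from, mv$to] + mv$rate
    for (s in setdiff(states, "F")) {
      m[s, "F"] <- death
      m[s, s] <- m[s, s] + 1 - sum(m[s, ])
    }
    m["F", ] <- 0; m["F", "F"] <- 1
    m
  }

  make_rates <- function(g, t, jit) {
    lapply(seq_along(base_moves), function(i) {
      mv <- base_moves[[i]]
      r <- mv[[3]] * jit[i]
      r <- r * switch(mv[[4]],
                      worsen = prog_mult[[g]] * type_prog[[t]],
                      relapse = prog_mult[[g]] * type_prog[[t]],
                      heal = heal_mult[[g]] * type_heal[[t]],
                      improve = heal_mult[[g]])
      list(from = mv[[1]], to = mv[[2]], rate = r, kind = mv[[4]])
    })
  }

  scit_rates <- function(rates) {
    lapply(rates, function(mv) {
      mv$rate <- mv$rate * switch(mv$kind,
                                  heal = 1 + 2 * effect_size,
                                  improve = 1 + effect_size,
                                  1 - 0.7 * effect_size)
      mv
    })
  }

  set <- with_seed(seed, {
    out <- list()
    for (g in age_groups()) for (t in allergy_types()) {
      jit <- if (jitter) stats::runif(length(base_moves), 0.9, 1.1)
             else rep(1, length(base_moves))
      st <- make_rates(g, t, jit)
      out[[paste(g, t, "ST", sep = ".")]] <- build(st, mort[[g]])
      out[[paste(g, t, "SCIT", sep = ".")]] <- build(scit_rates(st), mort[[g]])
    }
    out
  })
  set <- validate_transition_set(set)
  # self-check of the SCIT-vs-ST qualitative contract
  for (g in age_groups()) for (t in allergy_types()) {
    st <- set[[paste(g, t, "ST", sep = ".")]]
    sc <- set[[paste(g, t, "SCIT", sep = ".")]]
    if (any(sc[diseased_states(), "E"] < st[diseased_states(), "E"] - 1e-12))
      stop("internal error: SCIT remission below ST for ", g, "/", t)
    worsen <- cbind(c("A", "B", "C"), c("B", "C", "D"))
    if (any(sc[worsen] > st[worsen] + 1e-12))
      stop("internal error: SCIT progression above ST for ", g, "/", t)
  }
  attr(set, "provenance") <- "synthetic"
  set
}

#' Self-contained fixture configurations
#'
#' Complete, runnable parameter sets for testing and examples.
#' \describe{
#'   \item{toy}{3-year horizon 2011-2013, 1,000 persons at each single age
#'     6-12 and nobody else, all disease seasonal — so only the
#'     children/seasonal strata are populated and every number is small
#'     enough to check by hand (prevalence AR 10%, AA 5%).}
#'   \item{desk}{full 2011-2050 horizon, synthetic projection of 64 million
#'     persons aged 6-65 with a -0.4%/year youth-declining trend, and the
#'     published point values for prevalence, costs, SCIT prices and
#'     discounting.}
#' }
#' Both use synthetic transition matrices ([default_transition_params()]),
#' tagged as such in the provenance field.
#'
#' @param scale `"toy"` or `"desk"`.
#' @param seed RNG seed passed to the generators.
#' @param effect_size SCIT benefit scale for the synthetic matrices.
#' @return [model_params()] object.
#' @export
#' @examples
#' params <- make_fixture_config("toy", seed = 1)
#' params$horizon
make_fixture_config <- function(scale = c("toy", "desk"), seed = 1,
                                effect_size = 0.5) {
  scale <- match.arg(scale)
  mats <- default_transition_params(effect_size = effect_size, seed = seed)
  if (scale == "toy") {
    proj <- expand.grid(year = 2011:2013, age = 0:100)
    proj <- proj[order(proj$year, proj$age), ]
    proj$count <- ifelse(proj$age %in% 6:12, 1000, 0)
    model_params(projection = proj,
                 matrices = mats,
                 horizon = 2011:2013,
                 prevalence = prevalence_table(
                   ar = c(children = 0.10, adolescents = 0, adults = 0),
                   aa = c(children = 0.05, adolescents = 0, adults = 0),
                   seasonal_share = 1.0),
                 provenance = c("synthetic", "toy"))
  } else {
    proj <- generate_population_projection(64e6, annual_trend = -0.004,
                                           age_profile = "youth-declining",
                                           seed = seed, jitter_sd = 0.02)
    model_params(projection = proj,
                 matrices = mats,
                 horizon = 2011:2050,
                 provenance = c("synthetic", "desk"))
  }
}
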