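#' Parameter ranges for probabilistic sensitivity analysis
#'
#' Low/high bounds per uncertain input, on the scale of the point value.
#' Defaults are the published probabilistic ranges: AR prevalence
#' 3-7% / 10-20% / 15-20%, AA 2-5% / 4-7% / 2-5% (children / adolescents /
#' adults), seasonal share 45-75%, the bracketed state-cost ranges per age
#' group, SCIT yearly cost 262-502 (year 1) and 262-480 Euro (years 2-3),
#' and discount rate 1.5-2.5% p.a. The sampled SCIT cost is the mean yearly
#' drug cost (the published range spans the preseasonal and perennial
#' prices). `transition_perturbation` scales a multiplicative jitter of the
#' transition-matrix rows; its default range is degenerate at 0 (off), since
#' no published dispersion exists for the transition probabilities.
#'
#' @param ... Named length-2 numeric vectors `c(low, high)` overriding
#'   individual defaults.
#' @return Named list of class `parameter_ranges`.
#' @export
#' @examples
#' r <- parameter_ranges()
#' r$discount_rate
parameter_ranges <- function(...) {
  defaults <- list(
    prev_ar_children = c(0.03, 0.07),
    prev_ar_adolescents = c(0.10, 0.20),
    prev_ar_adults = c(0.15, 0.20),
    prev_aa_children = c(0.02, 0.05),
    prev_aa_adolescents = c(0.04, 0.07),
    prev_aa_adults = c(0.02, 0.05),
    seasonal_share = c(0.45, 0.75),
    cost_children_A = c(19, 35), cost_children_B = c(83, 155),
    cost_children_C = c(197, 367), cost_children_D = c(312, 580),
    cost_adolescents_A = c(13, 23), cost_adolescents_B = c(68, 126),
    cost_adolescents_C = c(181, 337), cost_adolescents_D = c(309, 575),
    cost_adults_A = c(6, 10), cost_adults_B = c(55, 103),
    cost_adults_C = c(159, 295), cost_adults_D = c(309, 575),
    scit_cost_year1 = c(262, 502),
    scit_cost_year2 = c(262, 480),
    scit_cost_year3 = c(262, 480),
    discount_rate = c(0.015, 0.025),
    transition_perturbation = c(0, 0)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  for (nm in names(defaults)) {
    r <- defaults[[nm]]
    if (length(r) != 2 || anyNA(r) || r[1] > r[2])
      stop("range for ", nm, " must be c(low, high) with low <= high")
  }
  structure(defaults, class = "parameter_ranges")
}

#' Draw one parameter set
#'
#' Independent uniform draws within each `[low, high]` bound. A degenerate
#' range always returns its single value without consuming randomness
#' differently. Draws are reproducible under a fixed seed.
#'
#' @param ranges [parameter_ranges()].
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return Named numeric vector, one value per parameter.
#' @export
sample_parameters <- function(ranges, seed = NULL) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  with_seed(seed, {
    vapply(ranges, function(r) stats::runif(1, r[1], r[2]), numeric(1))
  })
}

# Perturb transition matrices: rows A-E get a multiplicative jitter of
# scale s on every entry and are renormalized to sum 1; death stays
# absorbing.
perturb_transition_set <- function(set, scale) {
  if (scale <= 0) return(set)
  out <- lapply(set, function(m) {
    for (s in setdiff(disease_states(), "F")) {
      row <- m[s, ] * stats::runif(6, 1 - scale, 1 + scale)
      m[s, ] <- row / sum(row)
    }
    m
  })
  validate_transition_set(out)
}

#' Apply a sampled parameter set to a model configuration
#'
#' Returns a copy of `params` with prevalences, seasonal share, state
#' costs, SCIT costs, discount rate — and, if the sampled
#' `transition_perturbation` scale is positive, jittered transition
#' matrices — replaced by the drawn values. Any pre-computed incidence
#' schedule is dropped (it must be recalibrated for the new prevalences).
#'
#' @param params [model_params()].
#' @param draws Named vector from [sample_parameters()].
#' @param matrix_seed Seed for the transition-matrix jitter.
#' @return Modified [model_params()].
#' @export
apply_parameters <- function(params, draws, matrix_seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  g <- age_groups()
  prev <- prevalence_table(
    ar = stats::setNames(draws[paste0("prev_ar_", g)], g),
    aa = stats::setNames(draws[paste0("prev_aa_", g)], g),
    seasonal_share = unname(draws["seasonal_share"]))
  costs <- params$costs
  for (gg in g) for (s in diseased_states())
    costs[gg, s] <- draws[paste0("cost_", gg, "_", s)]
  yearly <- unname(draws[paste0("scit_cost_year", 1:3)])
  mats <- params$matrices
  pscale <- unname(draws["transition_perturbation"])
  if (!is.na(pscale) && pscale > 0)
    mats <- with_seed(matrix_seed, perturb_transition_set(mats, pscale))
  model_params(projection = params$projection,
               matrices = mats,
               horizon = params$horizon,
               prevalence = prev,
               ar_split = params$ar_split, aa_split = params$aa_split,
               onset_split = params$onset_split,
               costs = costs,
               scit_costs = scit_cost_schedule(preseasonal = yearly,
                                               perennial = yearly,
                                               mean_mode = params$scit_costs$mean_mode),
               discount = discount_spec(rate = unname(draws["discount_rate"]),
                                        base_year = params$discount$base_year),
               allocation = params$allocation,
               report_undiscounted = params$report_undiscounted,
               incidence = NULL,
               provenance = union(params$provenance, "psa"))
}

# Deterministic per-replicate sub-seed, kept inside 32-bit integer range.
psa_rep_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) * 131071 + rep * 7919) %% 2147483647)
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs every scenario `n_reps` times under parameter sets drawn from
#' `ranges`, with common random numbers: replicate `r` uses one shared
#' parameter draw (and one shared recalibrated incidence schedule) for all
#' scenarios, so scenario differences within a replicate reflect policy, not
#' sampling noise. Reported outputs per scenario are the mean-annual
#' diseased total, total discounted cost and discounted SCIT cost; the
#' summary gives their mean and standard deviation over replicates.
#'
#' @param specs List of [scenario_spec()] (default [builtin_scenarios()]).
#' @param params [model_params()] holding the point configuration.
#' @param ranges [parameter_ranges()].
#' @param n_reps Number of replicates (>= 2; the reference analysis uses
#'   1,000).
#' @param seed Master seed; replicate `r` uses a sub-seed derived from it,
#'   so the first `k` replicates of a longer run equal a run of length `k`.
#' @return data.frame of class `psa_summary` with columns `scenario`,
#'   `output`, `mean`, `sd`, `n_reps`, `seed`. Attributes: `replicates`
#'   (array n_reps x scenario x output) and `samples` (matrix of all
#'   parameter draws).
#' @export
run_psa <- function(specs = builtin_scenarios(), params, ranges = parameter_ranges(),
                    n_reps = 1000, seed = 1) {
  stopifnot(inherits(params, "model_params"))
  if (n_reps < 2) stop("n_reps must be at least 2")
  outputs <- c("diseased_total", "total_cost", "scit_cost")
  nm <- vapply(specs, `[[`, "", "name")
  reps <- array(NA_real_, dim = c(n_reps, length(specs), length(outputs)),
                dimnames = list(NULL, nm, outputs))
  samples <- matrix(NA_real_, nrow = n_reps, ncol = length(ranges),
                    dimnames = list(NULL, names(ranges)))
  for (r in seq_len(n_reps)) {
    rs <- psa_rep_seed(seed, r)
    res <- tryCatch({
      draws <- sample_parameters(ranges, seed = rs)
      samples[r, ] <- draws
      params_r <- apply_parameters(params, draws, matrix_seed = rs)
      incidence <- calibrate_incidence(params_r)
      lapply(specs, run_scenario, params = params_r, incidence = incidence)
    }, error = function(e)
      stop("PSA replicate ", r, " (sub-seed ", rs, ") failed: ",
           conditionMessage(e), call. = FALSE))
    for (j in seq_along(specs)) {
      m <- run_means(res[[j]])
      reps[r, j, ] <- c(m["mean_annual_diseased"], m["mean_annual_cost"],
                        m["mean_annual_scit_cost"])
    }
  }
  rows <- expand.grid(output = outputs, scenario = nm, stringsAsFactors = FALSE)
  out <- data.frame(scenario = rows$scenario, output = rows$output,
                    mean = mapply(function(s, o) mean(reps[, s, o]),
                                  rows$scenario, rows$output),
                    sd = mapply(function(s, o) stats::sd(reps[, s, o]),
                                rows$scenario, rows$output),
                    n_reps = n_reps, seed = seed, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, replicates = reps, samples = samples,
            class = c("psa_summary", "data.frame"))
}

#' @export
print.psa_summary <- function(x, ...) {
  cat("PSA summary (", x$n_reps[1], " replicates, seed ", x$seed[1],
      "); mean-annual outputs, mean +/- SD:\n", sep = "")
  shown <- data.frame(scenario = x$scenario, output = x$output,
                      mean = signif(x$mean, 6), sd = signif(x$sd, 4))
  print(shown, row.names = FALSE)
  invisible(x)
}
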