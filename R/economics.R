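#' Annual state cost of a cohort configuration
#'
#' Sum over strata and severity states of person-count times the age-group
#' state cost. The healthy state E and death F contribute nothing.
#'
#' @param cohorts Cohort matrix.
#' @param costs State-cost matrix ([cost_table()]).
#' @return Euro per year.
#' @export
#' @examples
#' cohorts <- empty_cohorts()
#' cohorts["adults.seasonal.ST", "A"] <- 100
#' annual_state_cost(cohorts)  # 100 x 8 Euro
annual_state_cost <- function(cohorts, costs = cost_table()) {
  validate_cohorts(cohorts)
  costs <- cost_table(costs)
  groups <- split_stratum_id(rownames(cohorts))$group
  occupied <- colSums(cohorts) > 0
  if (any(occupied[diseased_states()] & !diseased_states() %in% colnames(costs)))
    stop("missing cost entry for an occupied state")
  by_group <- rowsum(cohorts[, diseased_states(), drop = FALSE], groups)
  sum(by_group * costs[rownames(by_group), , drop = FALSE])
}

# SCIT drug cost of the current SCIT-arm occupancy for one year.
# Dead persons (state F) pay nothing; persons who reached E mid-course are
# assumed to complete the course and keep paying.
annual_scit_cost <- function(cohorts, schedule) {
  parts <- split_stratum_id(rownames(cohorts))
  alive <- setdiff(disease_states(), "F")
  total <- 0
  for (ty in 1:3) {
    arm <- paste0("SCIT", ty)
    rows <- which(parts$arm == arm)
    if (length(rows) == 0) next
    if (schedule$mean_mode == "mean") {
      total <- total + sum(cohorts[rows, alive]) * scit_mean_cost(schedule, ty)
    } else {
      for (i in rows) {
        price <- if (parts$type[i] == "seasonal") schedule$preseasonal[ty] else schedule$perennial[ty]
        total <- total + sum(cohorts[i, alive]) * price
      }
    }
  }
  total
}

# Move SCIT sub-cohorts one therapy year forward: year 3 completers go to
# the POST arm (ST dynamics, no further SCIT cost, no re-treatment).
promote_scit_arms <- function(cohorts) {
  out <- cohorts
  for (g in age_groups()) for (t in allergy_types()) {
    s1 <- stratum_id(g, t, "SCIT1"); s2 <- stratum_id(g, t, "SCIT2")
    s3 <- stratum_id(g, t, "SCIT3"); po <- stratum_id(g, t, "POST")
    out[po, ] <- out[po, ] + out[s3, ]
    out[s3, ] <- out[s2, ]
    out[s2, ] <- out[s1, ]
    out[s1, ] <- 0
  }
  out
}

# Insert the year's incident entrants (new diseased persons) into the onset
# states A/B of their strata.
add_entrants <- function(cohorts, incidence, year, onset_split) {
  if (is.null(incidence)) return(cohorts)
  y <- as.character(year)
  if (!y %in% rownames(incidence)) return(cohorts)
  e <- incidence[y, ]
  hit <- which(e > 0)
  for (j in hit) {
    id <- colnames(incidence)[j]
    cohorts[id, c("A", "B")] <- cohorts[id, c("A", "B")] + e[j] * onset_split
  }
  cohorts
}

#' Run one policy scenario over the full horizon
#'
#' Deterministic cohort simulation: the prevalent pool is initialised in the
#' base year; each subsequent year the SCIT therapy-year arms are promoted
#' (completers to the post-SCIT arm), every stratum is advanced one Markov
#' cycle, sub-cohorts age between groups, and calibrated incident entrants
#' are added; then the year's SCIT allocation is applied and occupancies and
#' costs are recorded. Costs accrue on end-of-year occupancy (no half-cycle
#' correction) and are discounted to the base year.
#'
#' @param spec [scenario_spec()].
#' @param params [model_params()].
#' @param incidence Incidence schedule; defaults to `params$incidence`. Pass
#'   an explicit schedule (possibly all-zero) to skip calibration.
#' @return Object of class `run_result`: list with
#'   \describe{
#'     \item{scenario}{scenario name}
#'     \item{by_year}{data.frame with per-year `diseased_total`,
#'       `healed_total`, `scit_patients`, `state_cost`, `scit_cost`,
#'       `total_cost`, `total_cost_discounted` and `aged_out` (persons
#'       leaving the 6-65 range)}
#'     \item{occupancy}{3-D array year x stratum x state (persons)}
#'     \item{provenance}{input provenance tags}
#'   }
#' @export
run_scenario <- function(spec, params, incidence = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(params, "model_params"))
  if (is.null(incidence)) incidence <- params$incidence
  if (is.null(incidence)) incidence <- calibrate_incidence(params)
  years <- params$horizon
  ix <- engine_index()
  step <- function(what, year, expr) {
    tryCatch(expr, error = function(e)
      stop("year ", year, " [", what, "]: ", conditionMessage(e), call. = FALSE))
  }
  cohorts <- initial_prevalent_pool(params$projection, params$prevalence,
                                    base_year = years[1],
                                    ar_split = params$ar_split,
                                    aa_split = params$aa_split)
  occ <- array(0, dim = c(length(years), length(stratum_ids()), 6L),
               dimnames = list(as.character(years), stratum_ids(), disease_states()))
  by_year <- data.frame(year = years, diseased_total = 0, healed_total = 0,
                        scit_patients = 0, state_cost = 0, scit_cost = 0,
                        scit_cost_discounted = 0, total_cost = 0,
                        total_cost_discounted = 0, aged_out = 0)
  for (k in seq_along(years)) {
    y <- years[k]
    aged_out <- 0
    if (k > 1) {
      cohorts <- promote_scit_arms(cohorts)
      cohorts <- step("advance", y, eng_advance(cohorts, params$matrices))
      aged <- step("ageing", y, eng_age(cohorts))
      cohorts <- aged$cohorts
      aged_out <- aged$outflow
      cohorts <- add_entrants(cohorts, incidence, y, params$onset_split)
    }
    cohorts <- step("allocation", y,
                    allocate_scit(cohorts, spec, y, params$allocation))
    occ[k, , ] <- cohorts
    sc <- eng_state_cost(cohorts, params$costs)
    tc <- eng_scit_cost(cohorts, params$scit_costs)
    totals <- colSums(cohorts)
    by_year$diseased_total[k] <- sum(totals[diseased_states()])
    by_year$healed_total[k] <- totals[["E"]]
    by_year$scit_patients[k] <- sum(cohorts[unlist(ix$scit_rows),
                                            setdiff(disease_states(), "F")])
    by_year$state_cost[k] <- sc
    by_year$scit_cost[k] <- tc
    by_year$scit_cost_discounted[k] <- discount(tc, y, params$discount)
    by_year$total_cost[k] <- sc + tc
    by_year$total_cost_discounted[k] <- discount(sc + tc, y, params$discount)
    by_year$aged_out[k] <- aged_out
  }
  structure(list(scenario = spec$name, by_year = by_year, occupancy = occ,
                 report_undiscounted = params$report_undiscounted,
                 provenance = params$provenance),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  yr <- x$by_year
  cat("<run_result> scenario: ", x$scenario, "\n", sep = "")
  cat("  years ", min(yr$year), "-", max(yr$year), "\n", sep = "")
  cat(sprintf("  mean annual diseased: %s persons\n",
              format(round(mean(yr$diseased_total)), big.mark = ",")))
  cat(sprintf("  mean annual total cost (discounted): %s Euro\n",
              format(round(mean(yr$total_cost_discounted)), big.mark = ",")))
  cat(sprintf("  mean annual SCIT cost (undiscounted): %s Euro\n",
              format(round(mean(yr$scit_cost)), big.mark = ",")))
  cat("  provenance: ", paste(x$provenance, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Mean-annual aggregates of one run, on the configured cost basis.
run_means <- function(result) {
  yr <- result$by_year
  cost <- if (isTRUE(result$report_undiscounted)) yr$total_cost else yr$total_cost_discounted
  scit <- if (isTRUE(result$report_undiscounted)) yr$scit_cost else yr$scit_cost_discounted
  c(mean_annual_cost = mean(cost),
    mean_annual_scit_cost = mean(scit),
    mean_annual_diseased = mean(yr$diseased_total),
    mean_annual_healed = mean(yr$healed_total))
}

#' Run several scenarios on shared calibrated inputs
#'
#' Calibrates the incidence schedule once (no-SCIT baseline) and runs every
#' scenario against it, so scenario differences reflect policy only.
#'
#' @param specs List of [scenario_spec()] (default: [builtin_scenarios()]).
#' @param params [model_params()].
#' @return Named list of `run_result` objects.
#' @export
run_scenarios <- function(specs = builtin_scenarios(), params) {
  incidence <- params$incidence
  if (is.null(incidence)) incidence <- calibrate_incidence(params)
  out <- lapply(specs, run_scenario, params = params, incidence = incidence)
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' Incremental cost-effectiveness ratio
#'
#' Additional mean annual cost divided by additional mean annual healed (or
#' avoided) patients versus the comparator, rounded to the nearest integer
#' Euro for reporting. A scenario that saves money while healing more
#' patients is `"dominant"` — no ratio is printed for it.
#'
#' @param delta_cost Mean annual cost difference, Euro/year.
#' @param delta_healed Mean annual additional healed patients, persons/year;
#'   must be strictly positive.
#' @return Integer Euro per additionally healed patient, or the string
#'   `"dominant"` when `delta_cost < 0`.
#' @export
#' @examples
#' icer(98964793, 288213)   # 343
#' icer(-1250059, 32794)    # "dominant"
icer <- function(delta_cost, delta_healed) {
  stopifnot(length(delta_cost) == 1, length(delta_healed) == 1)
  if (!is.finite(delta_healed) || delta_healed <= 0)
    stop("ICER undefined: delta_healed must be strictly positive")
  if (delta_cost < 0) return("dominant")
  round(delta_cost / delta_healed)
}

#' Compare scenario runs to the status quo
#'
#' For every non-baseline scenario, the difference in mean annual cost and
#' mean annual healed patients versus the status quo, and the resulting
#' incremental cost-effectiveness ratio (`"dominant"` for cost-saving
#' scenarios with superior effect, `"undefined"` where the effect difference
#' is not positive).
#'
#' @param results Named list of `run_result` objects containing `baseline`.
#' @param baseline Name of the comparator (default `"status_quo"`).
#' @return data.frame of class `scenario_comparison` with columns
#'   `scenario`, `delta_mean_annual_cost`, `delta_mean_annual_healed`,
#'   `icer`, `icer_label`.
#' @export
compare_to_status_quo <- function(results, baseline = "status_quo") {
  if (!baseline %in% names(results))
    stop("baseline scenario '", baseline, "' missing from results (have: ",
         paste(names(results), collapse = ", "), ")")
  base <- run_means(results[[baseline]])
  others <- setdiff(names(results), baseline)
  rows <- lapply(others, function(nm) {
    m <- run_means(results[[nm]])
    dc <- unname(m["mean_annual_cost"] - base["mean_annual_cost"])
    dh <- unname(m["mean_annual_healed"] - base["mean_annual_healed"])
    if (dh > 0) {
      r <- icer(dc, dh)
      if (identical(r, "dominant")) {
        val <- NA_real_; lab <- "dominant"
      } else {
        val <- r; lab <- as.character(r)
      }
    } else {
      val <- NA_real_; lab <- "undefined"
    }
    data.frame(scenario = nm, delta_mean_annual_cost = dc,
               delta_mean_annual_healed = dh, icer = val, icer_label = lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Differences vs. status quo (mean annual, Euro / persons):\n")
  shown <- data.frame(scenario = x$scenario,
                      delta_cost = round(x$delta_mean_annual_cost),
                      delta_healed = round(x$delta_mean_annual_healed),
                      cost_per_healed = x$icer_label)
  print(shown, row.names = FALSE)
  invisible(x)
}
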