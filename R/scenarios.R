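#' SCIT supply-rate schedule
#'
#' The supply rate is the proportion of eligible patients who start SCIT in a
#' given year, age group and allergy type. A schedule fixes the rates in the
#' start year (2011) and a target year; rates change linearly in between and
#' stay constant at the target level afterwards.
#'
#' Rates are stored as 3 x 2 matrices (age group x allergy type).
#'
#' @param rate_start,rate_target Numeric 3 x 2 matrices of proportions with
#'   rownames [age_groups()] and colnames [allergy_types()], or anything
#'   coercible via `rate_matrix()`.
#' @param target_year Calendar year at which `rate_target` is reached; must
#'   lie in (start_year, 2050].
#' @param start_year First year of the schedule (default 2011).
#' @return List of class `supply_schedule`.
#' @export
supply_schedule <- function(rate_start, rate_target, target_year,
                            start_year = 2011) {
  rate_start <- rate_matrix(rate_start)
  rate_target <- rate_matrix(rate_target)
  if (any(c(rate_start, rate_target) < 0) || any(c(rate_start, rate_target) > 1))
    stop("supply rates must lie in [0, 1]")
  if (target_year <= start_year || target_year > 2050)
    stop("target_year must lie in (", start_year, ", 2050]")
  structure(list(rate_start = rate_start, rate_target = rate_target,
                 start_year = start_year, target_year = target_year,
                 interpolation = "linear"),
            class = "supply_schedule")
}

#' @rdname supply_schedule
#' @param x Matrix, or vector of length 1 (uniform rate) or 6 (column-major
#'   group x type).
#' @export
rate_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(identical(rownames(x), age_groups()),
              identical(colnames(x), allergy_types()))
    return(x)
  }
  if (length(x) == 1L) x <- rep(x, 6L)
  matrix(as.numeric(x), nrow = 3, ncol = 2,
         dimnames = list(age_groups(), allergy_types()))
}

#' Interpolated SCIT supply rate
#'
#' Linear interpolation between the start-year and target-year rates,
#' constant at the target level after the target year.
#'
#' @param schedule [supply_schedule()].
#' @param group Age group code.
#' @param type Allergy type code.
#' @param year Calendar year within the modelled range (start year to 2050).
#' @return Proportion in \[0, 1\]. Vectorised over `year`.
#' @export
#' @examples
#' sq <- builtin_scenarios()$status_quo
#' supply_rate(sq$schedule, "adults", "seasonal", 2030)
supply_rate <- function(schedule, group, type, year) {
  stopifnot(inherits(schedule, "supply_schedule"),
            group %in% age_groups(), type %in% allergy_types())
  if (any(year < schedule$start_year) || any(year > 2050))
    stop("year must lie in [", schedule$start_year, ", 2050]")
  r0 <- schedule$rate_start[group, type]
  r1 <- schedule$rate_target[group, type]
  f <- pmin((year - schedule$start_year) /
              (schedule$target_year - schedule$start_year), 1)
  r0 + (r1 - r0) * f
}

#' Scenario specification
#'
#' A policy scenario is a supply-rate schedule plus the set of disease
#' states in which SCIT may be started (therapy-onset eligibility).
#'
#' @param name Scenario identifier.
#' @param schedule [supply_schedule()].
#' @param eligible_states Non-empty subset of the severity states
#'   `c("A","B","C","D")`.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(name, schedule, eligible_states) {
  stopifnot(inherits(schedule, "supply_schedule"))
  eligible_states <- as.character(eligible_states)
  if (length(eligible_states) == 0 ||
      !all(eligible_states %in% diseased_states()))
    stop("eligible_states must be a non-empty subset of A, B, C, D")
  structure(list(name = name, schedule = schedule,
                 eligible_states = sort(unique(eligible_states))),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, "\n", sep = "")
  cat("  therapy onset in states: ", paste(x$eligible_states, collapse = ", "), "\n", sep = "")
  cat("  supply rates ", x$schedule$start_year, " -> ", x$schedule$target_year,
      " (linear, constant thereafter)\n", sep = "")
  rates <- cbind(start = as.vector(x$schedule$rate_start),
                 target = as.vector(x$schedule$rate_target))
  rownames(rates) <- paste(rep(age_groups(), 2),
                           rep(allergy_types(), each = 3), sep = "/")
  print(round(rates, 4))
  invisible(x)
}

#' Built-in policy scenarios
#'
#' The five scenarios of the analysis. Baseline 2011 supply rates (expert
#' consensus): seasonal 5% / 15% / 20% and perennial 5% / 10% / 20% for
#' children / adolescents / adults.
#'
#' \describe{
#'   \item{status_quo}{Rates rise linearly to 2030 targets: seasonal
#'     10% / 20% / 30%, perennial 5% / 15% / 30%. Therapy onset only in the
#'     asthma states C and D.}
#'   \item{scenario_1}{The 2011 rates triple by 2020; onset in C, D.}
#'   \item{scenario_2}{Rates reach 75% in all groups by 2020; onset in C, D.}
#'   \item{scenario_3}{Status-quo schedule; onset extended to B, C, D.}
#'   \item{scenario_4}{Status-quo schedule; onset in all states A-D.}
#' }
#'
#' @return Named list of five [scenario_spec()] objects.
#' @export
#' @examples
#' names(builtin_scenarios())
builtin_scenarios <- function() {
  base_2011 <- rate_matrix(c(0.05, 0.15, 0.20,   # seasonal: chi, ado, adu
                             0.05, 0.10, 0.20))  # perennial
  sq_2030 <- rate_matrix(c(0.10, 0.20, 0.30,
                           0.05, 0.15, 0.30))
  sq_sched <- supply_schedule(base_2011, sq_2030, target_year = 2030)
  list(
    status_quo = scenario_spec("status_quo", sq_sched, c("C", "D")),
    scenario_1 = scenario_spec("scenario_1",
      supply_schedule(base_2011, 3 * base_2011, target_year = 2020), c("C", "D")),
    scenario_2 = scenario_spec("scenario_2",
      supply_schedule(base_2011, rate_matrix(0.75), target_year = 2020), c("C", "D")),
    scenario_3 = scenario_spec("scenario_3", sq_sched, c("B", "C", "D")),
    scenario_4 = scenario_spec("scenario_4", sq_sched, c("A", "B", "C", "D"))
  )
}

#' No-SCIT reference scenario
#'
#' A degenerate scenario with supply rate identically zero; used as the
#' baseline for incidence calibration.
#'
#' @return [scenario_spec()] with zero rates.
#' @export
null_scenario <- function() {
  scenario_spec("no_scit",
                supply_schedule(rate_matrix(0), rate_matrix(0), target_year = 2050),
                c("C", "D"))
}

#' Allocate patients to the SCIT arm for one year
#'
#' For each (age group, allergy type), the year's supply-rate fraction of
#' symptomatic-therapy patients currently in the scenario's eligible states
#' moves to SCIT therapy-year 1, keeping its disease state. Persons already
#' in a SCIT arm, persons in the post-SCIT arm (no re-treatment) and persons
#' in non-eligible states are untouched. Total persons are conserved exactly.
#'
#' Two readings of "proportion of patients who receive SCIT" are supported:
#' \describe{
#'   \item{flow (default)}{the rate is applied each year to the current
#'     ST pool in eligible states (yearly uptake of the untreated).}
#'   \item{stock}{the rate is a target share of all eligible-state patients
#'     under active SCIT; the arm is topped up from the ST pool to that
#'     level, limited by the available untreated persons.}
#' }
#'
#' @param cohorts Cohort matrix.
#' @param spec [scenario_spec()].
#' @param year Calendar year (sets the interpolated rate).
#' @param allocation `"flow"` or `"stock"`.
#' @return Cohort matrix after allocation.
#' @export
allocate_scit <- function(cohorts, spec, year, allocation = c("flow", "stock")) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(spec, "scenario_spec"))
  validate_cohorts(cohorts)
  out <- cohorts
  elig <- spec$eligible_states
  for (g in age_groups()) {
    for (t in allergy_types()) {
      rate <- supply_rate(spec$schedule, g, t, year)
      if (rate < 0 || rate > 1) stop("supply rate outside [0, 1]")
      if (rate == 0) next
      st_id <- stratum_id(g, t, "ST")
      if (!st_id %in% rownames(out)) next
      pool <- out[st_id, elig]
      if (allocation == "flow") {
        moved <- rate * pool
      } else {
        arm_ids <- intersect(stratum_id(g, t, treatment_arms()), rownames(out))
        total_elig <- sum(out[arm_ids, elig])
        on_scit <- sum(out[intersect(stratum_id(g, t, scit_arms()), rownames(out)), elig])
        need <- max(rate * total_elig - on_scit, 0)
        avail <- sum(pool)
        moved <- if (avail > 0) pool * min(need / avail, 1) else pool * 0
      }
      scit1 <- stratum_id(g, t, "SCIT1")
      out[st_id, elig] <- out[st_id, elig] - moved
      out[scit1, elig] <- out[scit1, elig] + moved
    }
  }
  out
}

#' Read and write scenario files
#'
#' Scenarios are stored as declarative YAML: name, eligible states, target
#' year, and start/target rates per age group and allergy type.
#' `export_builtin_scenarios()` writes the five built-in scenarios to a
#' directory as reference files.
#'
#' @param spec [scenario_spec()].
#' @param path File path.
#' @return `read_scenario_yaml()`: a [scenario_spec()];
#'   writers return the path(s) invisibly.
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  mat_to_list <- function(m) {
    stats::setNames(lapply(allergy_types(), function(t)
      as.list(stats::setNames(as.numeric(m[, t]), age_groups()))), allergy_types())
  }
  yaml::write_yaml(list(
    name = spec$name,
    eligible_states = as.list(spec$eligible_states),
    start_year = spec$schedule$start_year,
    target_year = spec$schedule$target_year,
    rate_start = mat_to_list(spec$schedule$rate_start),
    rate_target = mat_to_list(spec$schedule$rate_target)
  ), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("name", "eligible_states", "start_year", "target_year",
            "rate_start", "rate_target")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("scenario file ", path, " is missing fields: ",
         paste(missing, collapse = ", "))
  list_to_mat <- function(l) {
    m <- rate_matrix(0)
    for (t in allergy_types()) for (g in age_groups()) {
      v <- l[[t]][[g]]
      if (is.null(v)) stop("scenario file ", path, ": missing rate for ", g, "/", t)
      m[g, t] <- as.numeric(v)
    }
    m
  }
  scenario_spec(raw$name,
                supply_schedule(list_to_mat(raw$rate_start),
                                list_to_mat(raw$rate_target),
                                target_year = raw$target_year,
                                start_year = raw$start_year),
                unlist(raw$eligible_states))
}

#' @rdname write_scenario_yaml
#' @param dir Output directory (created if absent).
#' @export
export_builtin_scenarios <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(builtin_scenarios(), function(s) {
    p <- file.path(dir, paste0(s$name, ".yaml"))
    write_scenario_yaml(s, p)
    p
  }, character(1))
  invisible(paths)
}
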