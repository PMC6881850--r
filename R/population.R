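#' Population projection table
#'
#' The demographic input is a long table of projected person-counts with one
#' row per (calendar year, single age-year): columns `year`, `age`, `count`.
#' It must cover a contiguous range of calendar years and every single age 0
#' to 100 within each year, with non-negative counts. The bundled generator
#' ([generate_population_projection()]) emulates a national statistical
#' office projection for 2011-2050.
#'
#' @param proj Data frame with columns `year`, `age`, `count`.
#' @return `validate_projection()`: `proj` invisibly, or an error.
#' @export
validate_projection <- function(proj) {
  if (!is.data.frame(proj) || !all(c("year", "age", "count") %in% names(proj)))
    stop("projection must be a data.frame with columns year, age, count")
  if (anyNA(proj[c("year", "age", "count")]))
    stop("projection contains NA")
  if (any(proj$count < 0)) stop("projection counts must be non-negative")
  years <- sort(unique(proj$year))
  if (!identical(as.integer(years), as.integer(seq(min(years), max(years)))))
    stop("projection years must form a contiguous range")
  ages <- 0:100
  tab <- table(factor(proj$year, levels = years), factor(proj$age, levels = ages))
  if (any(tab != 1L))
    stop("projection must contain exactly one row per (year, age) for ages 0-100")
  invisible(proj)
}

#' @rdname validate_projection
#' @param path File path of a CSV with header `year,age,count`.
#' @export
read_projection_csv <- function(path) {
  proj <- utils::read.csv(path, colClasses = c("integer", "integer", "numeric"))
  if (!identical(names(proj), c("year", "age", "count")))
    stop("projection CSV must have header: year,age,count (got: ",
         paste(names(proj), collapse = ","), ")")
  validate_projection(proj)
  proj
}

#' @rdname validate_projection
#' @export
write_projection_csv <- function(proj, path) {
  validate_projection(proj)
  utils::write.csv(proj[c("year", "age", "count")], path, row.names = FALSE)
  invisible(path)
}

#' Population under risk by age group
#'
#' The population under risk is the population aged 6-65. Counts are summed
#' per single age-year over each age-group span (children 6-12, adolescents
#' 13-18, adults 19-65); ages below 6 and above 65 are excluded.
#'
#' @param proj Validated population projection.
#' @param year Calendar year covered by the projection.
#' @return Named numeric vector `c(children=, adolescents=, adults=)`.
#' @export
#' @examples
#' proj <- expand.grid(year = 2011, age = 0:100)
#' proj$count <- 1000
#' population_under_risk(proj, 2011)
population_under_risk <- function(proj, year) {
  if (!year %in% proj$year)
    stop("year ", year, " is outside the projection range ",
         min(proj$year), "-", max(proj$year))
  sub <- proj[proj$year == year, ]
  vapply(age_group_spans(),
         function(span) sum(sub$count[sub$age %in% span]),
         numeric(1))
}

#' Prevalence inputs
#'
#' Point prevalences of allergic rhinitis (AR) and allergic asthma (AA) per
#' age group, plus the share of seasonal disease. Defaults are the published
#' German inputs: AR 4.7% / 16.9% / 17.95% and AA 3.6% / 5.7% / 3.9% for
#' children / adolescents / adults, with 60% of cases seasonal. AA patients
#' are assumed to also have AR (states C and D include AR), so AA counts are
#' a subset of AR counts.
#'
#' @param ar,aa Named proportions per age group, in \[0, 1\].
#' @param seasonal_share Proportion of seasonal disease; the perennial share
#'   is its complement, so the two always sum to 1.
#' @return List of class `prevalence_table`.
#' @export
prevalence_table <- function(ar = c(children = 0.047, adolescents = 0.169, adults = 0.1795),
                             aa = c(children = 0.036, adolescents = 0.057, adults = 0.039),
                             seasonal_share = 0.60) {
  ar <- ar[age_groups()]; aa <- aa[age_groups()]
  if (anyNA(ar) || anyNA(aa))
    stop("ar and aa must be named proportions for ", paste(age_groups(), collapse = ", "))
  if (any(c(ar, aa, seasonal_share) < 0) || any(c(ar, aa, seasonal_share) > 1))
    stop("prevalences and seasonal_share must lie in [0, 1]")
  structure(list(ar = ar, aa = aa, seasonal_share = seasonal_share),
            class = "prevalence_table")
}

#' Initial prevalent pool
#'
#' Builds the sub-cohorts diseased at the start of the analysis from the
#' base-year population and prevalence data. Per age group, AA-prevalent
#' persons occupy the asthma states C/D and are subtracted from the AR count
#' (AA patients also have AR; counting both would double-count), the
#' remaining AR-only persons occupy A/B. Within-severity splits are
#' configurable (the published model does not state them; defaults 50/50).
#' Each group is divided into seasonal and perennial types by
#' `seasonal_share`, and everyone starts in the symptomatic-therapy arm:
#' SCIT uptake is applied later, year by year, by the scenario machinery.
#'
#' @param proj Validated population projection.
#' @param prev [prevalence_table()].
#' @param base_year First modelled year (default 2011).
#' @param ar_split Length-2 proportions over states A, B for AR-only persons.
#' @param aa_split Length-2 proportions over states C, D for AA persons.
#' @return Cohort matrix ([empty_cohorts()] layout).
#' @export
initial_prevalent_pool <- function(proj, prev, base_year = 2011,
                                   ar_split = c(0.5, 0.5),
                                   aa_split = c(0.5, 0.5)) {
  stopifnot(inherits(prev, "prevalence_table"))
  if (abs(sum(ar_split) - 1) > 1e-9 || abs(sum(aa_split) - 1) > 1e-9)
    stop("severity splits must sum to 1")
  pur <- population_under_risk(proj, base_year)
  cohorts <- empty_cohorts()
  shares <- c(seasonal = prev$seasonal_share, perennial = 1 - prev$seasonal_share)
  for (g in age_groups()) {
    aa_n <- pur[[g]] * prev$aa[[g]]
    ar_only <- max(pur[[g]] * prev$ar[[g]] - aa_n, 0)
    for (t in allergy_types()) {
      id <- stratum_id(g, t, "ST")
      cohorts[id, c("A", "B")] <- ar_only * shares[[t]] * ar_split
      cohorts[id, c("C", "D")] <- aa_n * shares[[t]] * aa_split
    }
  }
  cohorts
}

#' Age sub-cohorts between groups
#'
#' Once per yearly cycle a uniform-age fraction of each group moves up:
#' 1/7 of children (7 single ages) to adolescents, 1/6 of adolescents to
#' adults, and 1/47 of adults leaves the population under risk (turns 66).
#' The fractions apply to every health state and arm alike. Total persons
#' are conserved apart from the adult outflow, which is returned in the
#' `"outflow"` attribute.
#'
#' @param cohorts Cohort matrix.
#' @return Cohort matrix with attribute `outflow` (persons leaving the
#'   modelled ages, by state).
#' @export
age_cohorts <- function(cohorts) {
  validate_cohorts(cohorts)
  out <- cohorts
  parts <- split_stratum_id(rownames(cohorts))
  frac <- c(children = 1 / 7, adolescents = 1 / 6, adults = 1 / 47)
  nxt <- c(children = "adolescents", adolescents = "adults")
  outflow <- stats::setNames(numeric(6), disease_states())
  for (i in seq_len(nrow(cohorts))) {
    g <- parts$group[i]
    moved <- cohorts[i, ] * frac[[g]]
    out[i, ] <- out[i, ] - moved
    if (g == "adults") {
      outflow <- outflow + moved
    } else {
      to <- stratum_id(nxt[[g]], parts$type[i], parts$arm[i])
      if (!to %in% rownames(cohorts))
        stop("ageing target stratum missing: ", to)
      out[to, ] <- out[to, ] + moved
    }
  }
  structure(out, outflow = outflow)
}

#' Yearly incidence schedule
#'
#' New diseased persons entering the model each year after the base year,
#' as a (year x stratum) matrix of person-counts. The model inserts entrants
#' into the onset states A/B according to the configured onset split. In the
#' default pipeline the schedule is produced by [calibrate_incidence()];
#' entrants arrive in the children strata of the symptomatic-therapy arm
#' (onset at the youngest modelled ages).
#'
#' @param years Calendar years the schedule covers.
#' @return Zero matrix of class `incidence_schedule`, rows named by year,
#'   columns by stratum id.
#' @export
incidence_schedule <- function(years) {
  structure(matrix(0, nrow = length(years), ncol = length(stratum_ids()),
                   dimnames = list(as.character(years), stratum_ids())),
            class = c("incidence_schedule", "matrix", "array"))
}

#' Calibrate incidence to the demographic trend
#'
#' The model's incidence assumption is that, in the absence of SCIT, the
#' relative change in total diseased persons between the base year and any
#' later year equals the relative change in the population under risk over
#' the same period. This routine finds the yearly entrant counts that
#' realise that assumption: it repeatedly runs the no-SCIT baseline and
#' adjusts each year's entrants by the residual between achieved and target
#' diseased totals (fixed-point iteration), until every modelled year is
#' within `tol` relative deviation of its target.
#'
#' Entrant counts are clamped at zero: if the natural dynamics already leave
#' more diseased persons than the target (which negative incidence would be
#' needed to undo), the iteration cannot converge and errors out.
#'
#' @param params [model_params()] object.
#' @param tol Relative tolerance on the yearly diseased total (default
#'   0.005); must be strictly positive.
#' @param max_iter Maximum fixed-point iterations (default 100).
#' @return An [incidence_schedule()] with entrants in the children ST strata,
#'   split seasonal/perennial by the configured share. Attribute
#'   `achieved_ratio` records the baseline diseased trajectory relative to
#'   the base year.
#' @export
calibrate_incidence <- function(params, tol = 0.005, max_iter = 100) {
  if (tol <= 0) stop("tol must be strictly positive (exact calibration is unattainable)")
  years <- params$horizon
  later <- years[-1]
  pur <- vapply(years, function(y) sum(population_under_risk(params$projection, y)),
                numeric(1))
  pool <- initial_prevalent_pool(params$projection, params$prevalence,
                                 base_year = years[1],
                                 ar_split = params$ar_split, aa_split = params$aa_split)
  d0 <- diseased_total(pool)
  if (d0 <= 0) stop("no diseased persons in the base year; nothing to calibrate")
  target <- d0 * pur / pur[1]
  names(target) <- as.character(years)

  sched <- incidence_schedule(later)
  share <- c(seasonal = params$prevalence$seasonal_share,
             perennial = 1 - params$prevalence$seasonal_share)
  cols <- stratum_id("children", allergy_types(), "ST")

  # Each iteration sweeps the no-SCIT baseline forward in time, updating the
  # current year's entrants by the residual to its target before moving on
  # (Gauss-Seidel flavour of the fixed-point update): entrants added in year
  # y count towards year y's diseased total directly, so unless the zero
  # clamp binds, one sweep lands on target and the next confirms it.
  for (iter in seq_len(max_iter)) {
    cohorts <- pool
    for (k in seq_along(later)) {
      adv <- eng_age(eng_advance(cohorts, params$matrices))
      cohorts <- adv$cohorts
      y <- as.character(later[k])
      resid <- target[[y]] - sum(colSums(cohorts)[diseased_states()])
      e <- max(resid, 0)
      sched[y, cols[1]] <- e * share[["seasonal"]]
      sched[y, cols[2]] <- e * share[["perennial"]]
      cohorts <- add_entrants(cohorts, sched, later[k], params$onset_split)
    }
    res <- run_scenario(null_scenario(), params, incidence = sched)
    achieved <- stats::setNames(res$by_year$diseased_total, res$by_year$year)
    dev <- abs(achieved - target) / target
    if (max(dev) <= tol) {
      attr(sched, "achieved_ratio") <- unname(achieved / achieved[1])
      attr(sched, "iterations") <- iter
      return(sched)
    }
  }
  stop("incidence calibration did not converge within ", max_iter,
       " iterations (max relative deviation ", signif(max(dev), 3), ")")
}
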