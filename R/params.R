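#' Payer-perspective yearly state costs
#'
#' Annual third-party-payer cost of spending one cycle (one year) in each
#' severity state, by age group, in Euro. The healthy state E and death F
#' cost nothing. Defaults are the published German inputs:
#' children 27 / 119 / 282 / 446, adolescents 18 / 97 / 259 / 442 and
#' adults 8 / 79 / 227 / 442 Euro for states A / B / C / D.
#'
#' @param x 3 x 4 numeric matrix (rows [age_groups()], columns A-D), or
#'   `NULL` for the defaults.
#' @return Validated 3 x 4 cost matrix (Euro/person-year).
#' @export
cost_table <- function(x = NULL) {
  if (is.null(x)) {
    x <- matrix(c(27, 119, 282, 446,
                  18,  97, 259, 442,
                   8,  79, 227, 442),
                nrow = 3, byrow = TRUE,
                dimnames = list(age_groups(), diseased_states()))
  }
  stopifnot(is.matrix(x), identical(rownames(x), age_groups()),
            identical(colnames(x), diseased_states()))
  if (anyNA(x) || any(x < 0)) stop("state costs must be non-negative")
  x
}

#' SCIT drug-cost schedule
#'
#' Pharmacy selling prices of the allergen preparation per therapy year,
#' in Euro, for preseasonal (262 / 262 / 262) and perennial
#' (502 / 480 / 480) application. The default costing mode charges every
#' treated patient the arithmetic mean of the two application forms —
#' 382 Euro in therapy year 1 and 371 Euro in years 2-3; mode `"by_type"`
#' instead charges seasonal strata the preseasonal price and perennial
#' strata the perennial price.
#'
#' @param preseasonal,perennial Length-3 numeric vectors, Euro per therapy
#'   year 1-3.
#' @param mean_mode `"mean"` (default) or `"by_type"`.
#' @return List of class `scit_cost_schedule`.
#' @export
scit_cost_schedule <- function(preseasonal = c(262, 262, 262),
                               perennial = c(502, 480, 480),
                               mean_mode = c("mean", "by_type")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(length(preseasonal) == 3, length(perennial) == 3,
            all(preseasonal >= 0), all(perennial >= 0))
  structure(list(preseasonal = as.numeric(preseasonal),
                 perennial = as.numeric(perennial),
                 mean_mode = mean_mode),
            class = "scit_cost_schedule")
}

#' Mean SCIT drug cost for a therapy year
#'
#' Arithmetic mean of the preseasonal and perennial cost of the given
#' therapy year. With the default prices this yields 382 Euro in year 1 and
#' 371 Euro in years 2 and 3.
#'
#' @param schedule [scit_cost_schedule()].
#' @param therapy_year 1, 2 or 3.
#' @return Euro per treated person-year.
#' @export
#' @examples
#' scit_mean_cost(scit_cost_schedule(), 1)
scit_mean_cost <- function(schedule, therapy_year) {
  stopifnot(inherits(schedule, "scit_cost_schedule"))
  if (!therapy_year %in% 1:3) stop("therapy_year must be 1, 2 or 3")
  (schedule$preseasonal[therapy_year] + schedule$perennial[therapy_year]) / 2
}

#' Discount specification
#'
#' Future costs are discounted to the base year at a fixed annual rate
#' (default 2% per annum, the conventional German health-economic rate).
#'
#' @param rate Annual discount rate, in \[0, 0.10\].
#' @param base_year Year to which costs are discounted (default 2011).
#' @return List of class `discount_spec`.
#' @export
discount_spec <- function(rate = 0.02, base_year = 2011) {
  if (rate < 0 || rate > 0.10) stop("discount rate must lie in [0, 0.10]")
  structure(list(rate = rate, base_year = base_year), class = "discount_spec")
}

#' Discount a cost to the base year
#'
#' `amount / (1 + rate)^(year - base_year)`.
#'
#' @param amount Euro (vectorised).
#' @param year Calendar year the cost occurs in; must not precede the base
#'   year.
#' @param spec [discount_spec()].
#' @return Present value in base-year Euro.
#' @export
#' @examples
#' discount(102, 2012, discount_spec(rate = 0.02, base_year = 2011))
discount <- function(amount, year, spec = discount_spec()) {
  stopifnot(inherits(spec, "discount_spec"))
  if (any(year < spec$base_year))
    stop("cannot discount a cost occurring before the base year ", spec$base_year)
  amount / (1 + spec$rate)^(year - spec$base_year)
}

#' Full model parameter set
#'
#' Bundles every input of one model run: the population projection, the
#' modelled horizon, prevalence and severity splits, cost inputs, discount
#' specification, the stratum transition matrices, and behavioural switches.
#'
#' @param projection Population projection data frame (see
#'   [validate_projection()]).
#' @param matrices Transition set (see [validate_transition_set()]).
#' @param horizon Contiguous calendar years to simulate (default 2011:2050).
#' @param prevalence [prevalence_table()].
#' @param ar_split,aa_split Within-severity splits of the prevalent pool
#'   over A/B resp. C/D (defaults 50/50; not published, synthetic choice).
#' @param onset_split Split of incident entrants over onset states A/B
#'   (default 50/50; not published, synthetic choice).
#' @param costs State-cost matrix ([cost_table()]).
#' @param scit_costs [scit_cost_schedule()].
#' @param discount [discount_spec()].
#' @param allocation `"flow"` or `"stock"` SCIT uptake semantics (see
#'   [allocate_scit()]).
#' @param report_undiscounted If `TRUE`, mean-annual summary figures use
#'   undiscounted yearly costs.
#' @param incidence Optional pre-computed [incidence_schedule()]; if `NULL`
#'   the run machinery calibrates one via [calibrate_incidence()].
#' @param provenance Character tags describing the origin of the inputs;
#'   synthetic inputs are tagged `"synthetic"` and the tag is propagated
#'   into every output file so generated dynamics are never mistaken for
#'   published ones.
#' @return List of class `model_params`.
#' @export
model_params <- function(projection,
                         matrices,
                         horizon = 2011:2050,
                         prevalence = prevalence_table(),
                         ar_split = c(0.5, 0.5),
                         aa_split = c(0.5, 0.5),
                         onset_split = c(0.5, 0.5),
                         costs = cost_table(),
                         scit_costs = scit_cost_schedule(),
                         discount = discount_spec(),
                         allocation = c("flow", "stock"),
                         report_undiscounted = FALSE,
                         incidence = NULL,
                         provenance = "synthetic") {
  allocation <- match.arg(allocation)
  validate_projection(projection)
  horizon <- as.integer(horizon)
  if (length(horizon) < 2 || !identical(horizon, seq(horizon[1], horizon[length(horizon)])))
    stop("horizon must be a contiguous range of at least two years")
  if (!all(horizon %in% unique(projection$year)))
    stop("projection does not cover the full horizon ",
         horizon[1], "-", horizon[length(horizon)])
  stopifnot(inherits(prevalence, "prevalence_table"),
            inherits(scit_costs, "scit_cost_schedule"),
            inherits(discount, "discount_spec"))
  if (discount$base_year != horizon[1])
    stop("discount base year must equal the first modelled year")
  for (s in list(ar_split, aa_split, onset_split))
    if (length(s) != 2 || abs(sum(s) - 1) > 1e-9 || any(s < 0))
      stop("splits must be length-2 non-negative proportions summing to 1")
  structure(list(projection = projection,
                 matrices = validate_transition_set(matrices),
                 horizon = horizon,
                 prevalence = prevalence,
                 ar_split = ar_split, aa_split = aa_split,
                 onset_split = onset_split,
                 costs = cost_table(costs),
                 scit_costs = scit_costs,
                 discount = discount,
                 allocation = allocation,
                 report_undiscounted = report_undiscounted,
                 incidence = incidence,
                 provenance = provenance),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  horizon: ", x$horizon[1], "-", x$horizon[length(x$horizon)],
      " (", length(x$horizon), " yearly cycles)\n", sep = "")
  pur <- population_under_risk(x$projection, x$horizon[1])
  cat("  population under risk (", x$horizon[1], "): ",
      format(round(sum(pur)), big.mark = ","), " persons\n", sep = "")
  cat("  seasonal share: ", x$prevalence$seasonal_share,
      "; discount rate: ", x$discount$rate, "/a; allocation: ",
      x$allocation, "\n", sep = "")
  cat("  incidence: ", if (is.null(x$incidence)) "to be calibrated" else "pre-computed", "\n", sep = "")
  cat("  provenance: ", paste(x$provenance, collapse = ", "), "\n", sep = "")
  invisible(x)
}
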