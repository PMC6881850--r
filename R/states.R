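#' Health states of the Markov model
#'
#' The model tracks six mutually exclusive health states per sub-cohort:
#' \describe{
#'   \item{A}{mild allergic rhinitis (AR)}
#'   \item{B}{moderate/severe AR}
#'   \item{C}{moderate/severe AR + mild allergic asthma (AA)}
#'   \item{D}{severe AR + moderate/severe AA}
#'   \item{E}{no symptoms / healthy}
#'   \item{F}{death (absorbing)}
#' }
#' The state order `A, B, C, D, E, F` is fixed here and used in every array,
#' matrix and file the package reads or writes. Severity is ordered
#' `A < B < C < D`; `E` and `F` sit outside the severity order. States `A`
#' through `D` count as "diseased", `E` as "healed".
#'
#' @return Character vector of the six state codes, in canonical order.
#' @export
#' @examples
#' disease_states()
disease_states <- function() c("A", "B", "C", "D", "E", "F")

#' @rdname disease_states
#' @export
diseased_states <- function() c("A", "B", "C", "D")

#' Age groups of the population under risk
#'
#' The population under risk is the German population aged 6 to 65 years,
#' split into children (6-12), adolescents (13-18) and adults (19-65).
#'
#' @return `age_groups()`: character vector of group codes.
#'   `age_group_spans()`: named list of inclusive integer age ranges.
#' @export
#' @examples
#' age_group_spans()
age_groups <- function() c("children", "adolescents", "adults")

#' @rdname age_groups
#' @export
age_group_spans <- function() {
  list(children = 6:12, adolescents = 13:18, adults = 19:65)
}

#' Allergy types and treatment arms
#'
#' Disease is either seasonal or perennial (default population split 60/40).
#' Treatment arms distinguish symptomatic therapy (`ST`), the three
#' SCIT therapy years (`SCIT1`, `SCIT2`, `SCIT3`) and `POST`, the
#' post-SCIT arm: persons who completed the 3-year course, follow ST
#' transition dynamics, incur no further SCIT cost, and are not re-treated.
#'
#' @return Character vector of codes.
#' @export
allergy_types <- function() c("seasonal", "perennial")

#' @rdname allergy_types
#' @export
treatment_arms <- function() c("ST", "SCIT1", "SCIT2", "SCIT3", "POST")

#' @rdname allergy_types
#' @export
scit_arms <- function() c("SCIT1", "SCIT2", "SCIT3")

#' Stratum identifiers
#'
#' A stratum is one sub-cohort: (age group, allergy type, treatment arm),
#' encoded as `"<group>.<type>.<arm>"`. The full stratification is the
#' Cartesian product 3 x 2 x 5 = 30 strata; every person-count in the model
#' belongs to exactly one stratum.
#'
#' @param group,type,arm Component codes; vectors are recycled.
#' @return `stratum_ids()`: all 30 ids; `stratum_id()`: the id(s) for the
#'   given components; `split_stratum_id()`: a data.frame with columns
#'   `group`, `type`, `arm`.
#' @export
#' @examples
#' stratum_id("children", "seasonal", "ST")
#' length(stratum_ids())
stratum_ids <- function() {
  grid <- expand.grid(arm = treatment_arms(), type = allergy_types(),
                      group = age_groups(), stringsAsFactors = FALSE)
  stratum_id(grid$group, grid$type, grid$arm)
}

#' @rdname stratum_ids
#' @export
stratum_id <- function(group, type, arm) {
  stopifnot(all(group %in% age_groups()), all(type %in% allergy_types()),
            all(arm %in% treatment_arms()))
  paste(group, type, arm, sep = ".")
}

#' @rdname stratum_ids
#' @export
split_stratum_id <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed stratum id: ", id[bad][1L])
  out <- data.frame(group = vapply(parts, `[`, "", 1L),
                    type  = vapply(parts, `[`, "", 2L),
                    arm   = vapply(parts, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$group %in% age_groups()),
            all(out$type %in% allergy_types()),
            all(out$arm %in% treatment_arms()))
  out
}

#' Empty cohort matrix
#'
#' Cohorts are stored as a numeric matrix of expected person-counts with one
#' row per stratum (all 30, canonical order) and one column per health state.
#' Counts are real-valued expectations, not integers: the cohort model is
#' deterministic.
#'
#' @return A 30 x 6 zero matrix with stratum rownames and state colnames.
#' @export
#' @examples
#' cohorts <- empty_cohorts()
#' cohorts["adults.seasonal.ST", "A"] <- 100
empty_cohorts <- function() {
  matrix(0, nrow = length(stratum_ids()), ncol = 6L,
         dimnames = list(stratum_ids(), disease_states()))
}

#' Validate a cohort matrix
#'
#' @param cohorts Numeric matrix as produced by [empty_cohorts()].
#' @return `cohorts`, invisibly, if valid; otherwise an error naming the
#'   violated condition.
#' @export
validate_cohorts <- function(cohorts) {
  if (!is.matrix(cohorts) || !is.numeric(cohorts))
    stop("cohorts must be a numeric matrix")
  if (!identical(colnames(cohorts), disease_states()))
    stop("cohort columns must be the states ", paste(disease_states(), collapse = ", "))
  if (is.null(rownames(cohorts)) || anyDuplicated(rownames(cohorts)))
    stop("cohort rows must carry unique stratum ids")
  split_stratum_id(rownames(cohorts))  # errors on malformed ids
  if (anyNA(cohorts) || any(cohorts < 0) || any(!is.finite(cohorts)))
    stop("cohort counts must be finite and non-negative")
  invisible(cohorts)
}

# Aggregate person-counts by state across all strata, optionally restricted
# to a subset of arms.
#' Totals over a cohort matrix
#'
#' `cohort_state_totals()` sums persons per state across strata;
#' `diseased_total()` is the total in states A-D, `healed_total()` the total
#' in state E.
#'
#' @param cohorts Cohort matrix.
#' @param arms Optional subset of treatment arms to include.
#' @return Named numeric vector per state, or a single total.
#' @export
cohort_state_totals <- function(cohorts, arms = NULL) {
  if (!is.null(arms)) {
    keep <- split_stratum_id(rownames(cohorts))$arm %in% arms
    cohorts <- cohorts[keep, , drop = FALSE]
  }
  colSums(cohorts)
}

#' @rdname cohort_state_totals
#' @export
diseased_total <- function(cohorts) {
  sum(cohort_state_totals(cohorts)[diseased_states()])
}

#' @rdname cohort_state_totals
#' @export
healed_total <- function(cohorts) {
  unname(cohort_state_totals(cohorts)["E"])
}
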