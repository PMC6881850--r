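#' Validate a yearly transition-probability matrix
#'
#' A transition matrix holds yearly probabilities `p(from -> to)` over the six
#' health states. It must be 6 x 6, entrywise in \[0, 1\], row-stochastic
#' (each row sums to 1 within 1e-9), and death must be absorbing: row `F` is
#' the unit vector on `F`.
#'
#' @param m Numeric 6 x 6 matrix. Dimnames, if present, must match
#'   [disease_states()] in order; missing dimnames are added.
#' @param label Optional name used in error messages.
#' @return `m` (with canonical dimnames), unchanged otherwise.
#' @export
#' @examples
#' validate_matrix(diag(6))
validate_matrix <- function(m, label = NULL) {
  tag <- if (is.null(label)) "" else paste0(" [", label, "]")
  if (!is.matrix(m) || !is.numeric(m) || !all(dim(m) == c(6L, 6L)))
    stop("transition matrix", tag, " must be a numeric 6x6 matrix")
  if (anyNA(m)) stop("transition matrix", tag, " contains NA")
  states <- disease_states()
  if (!is.null(dimnames(m)) &&
      (!identical(rownames(m), states) || !identical(colnames(m), states)))
    stop("transition matrix", tag, " dimnames must be states ",
         paste(states, collapse = ", "), " in order")
  dimnames(m) <- list(states, states)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("transition matrix%s has negative entry %s->%s (%.6g)",
                 tag, states[neg[1, 1]], states[neg[1, 2]], m[neg[1, , drop = FALSE]]))
  if (any(m > 1))
    stop("transition matrix", tag, " has entries > 1")
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > 1e-9)
  if (length(off) > 0)
    stop(sprintf("transition matrix%s row %s sums to %.12g, expected 1",
                 tag, states[off[1]], rs[off[1]]))
  f <- m["F", ]
  if (any(f[states != "F"] != 0) || f["F"] != 1)
    stop("transition matrix", tag, ": death is not absorbing (row F must be the unit vector on F)")
  m
}

#' Advance a cohort vector by one Markov cycle
#'
#' One cycle is one calendar year. The out-count for state `j` is
#' `sum_i v[i] * m[i, j]`; because the matrix is row-stochastic, total
#' persons (including state `F`) are conserved.
#'
#' @param v Named numeric vector of person-counts over [disease_states()],
#'   or an unnamed length-6 vector in canonical state order.
#' @param m Validated transition matrix.
#' @return Named numeric vector of person-counts after one cycle.
#' @export
#' @examples
#' v <- c(A = 100, B = 0, C = 0, D = 0, E = 0, F = 0)
#' advance_cycle(v, diag(6))
advance_cycle <- function(v, m) {
  if (length(v) != 6L) stop("cohort vector must have length 6")
  if (!is.null(names(v)) && !identical(names(v), disease_states()))
    stop("cohort vector names must be states ", paste(disease_states(), collapse = ", "))
  if (!all(dim(m) == c(6L, 6L))) stop("dimension mismatch: matrix is not 6x6")
  out <- as.numeric(v %*% m)
  names(out) <- disease_states()
  out
}

#' Advance all strata by one cycle
#'
#' Each stratum is advanced independently with its own transition matrix.
#' A stratum occupied in `cohorts` without a matrix in `matrices` is an
#' error, never silently skipped.
#'
#' @param cohorts Cohort matrix ([empty_cohorts()] layout or any subset of
#'   its rows).
#' @param matrices Named list mapping stratum id to a 6 x 6 transition
#'   matrix (e.g. from [strata_matrices()]).
#' @return Cohort matrix of the same shape, advanced one cycle.
#' @export
advance_stratified <- function(cohorts, matrices) {
  validate_cohorts(cohorts)
  ids <- rownames(cohorts)
  missing <- setdiff(ids, names(matrices))
  if (length(missing) > 0)
    stop("no transition matrix for stratum: ", paste(missing, collapse = ", "))
  out <- cohorts
  for (id in ids) {
    out[id, ] <- as.numeric(cohorts[id, , drop = FALSE] %*% matrices[[id]])
  }
  out
}

#' Transition-matrix set for the full stratification
#'
#' The model distinguishes transition dynamics by age group, allergy type and
#' treatment (SCIT vs. symptomatic therapy): 3 x 2 x 2 = 12 distinct
#' matrices. A `transition_set` is a named list with keys
#' `"<group>.<type>.<ST|SCIT>"`. `strata_matrices()` expands it to the
#' per-stratum mapping used by [advance_stratified()]: the three SCIT therapy
#' years share the SCIT matrix; the `POST` arm (completed course) follows the
#' ST matrix.
#'
#' @param set Named list of 12 transition matrices.
#' @return `validate_transition_set()`: the set, each matrix validated;
#'   `strata_matrices()`: named list over all 30 stratum ids.
#' @export
validate_transition_set <- function(set) {
  expected <- transition_set_keys()
  if (!setequal(names(set), expected))
    stop("transition set must have exactly the keys: ",
         paste(setdiff(expected, names(set)), collapse = ", "), " missing")
  for (k in expected) set[[k]] <- validate_matrix(set[[k]], label = k)
  set[expected]
}

#' @rdname validate_transition_set
#' @export
transition_set_keys <- function() {
  grid <- expand.grid(trt = c("ST", "SCIT"), type = allergy_types(),
                      group = age_groups(), stringsAsFactors = FALSE)
  paste(grid$group, grid$type, grid$trt, sep = ".")
}

#' @rdname validate_transition_set
#' @export
strata_matrices <- function(set) {
  set <- validate_transition_set(set)
  ids <- stratum_ids()
  parts <- split_stratum_id(ids)
  trt <- ifelse(parts$arm %in% scit_arms(), "SCIT", "ST")
  keys <- paste(parts$group, parts$type, trt, sep = ".")
  out <- set[keys]
  names(out) <- ids
  out
}
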