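# Internal fast paths for the yearly loop. These mirror the exported
# per-operation functions (advance_stratified, age_cohorts,
# annual_state_cost, annual_scit_cost) on the full canonical 30-stratum
# matrix, but precompute all index arithmetic once. Equivalence with the
# public operations is asserted in the test suite.

# Precomputed index structure for the canonical stratum layout.
engine_index <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ids <- stratum_ids()
    parts <- split_stratum_id(ids)
    trt <- ifelse(parts$arm %in% scit_arms(), "SCIT", "ST")
    mkey <- paste(parts$group, parts$type, trt, sep = ".")
    blocks <- split(seq_along(ids), mkey)
    child <- which(parts$group == "children")
    adol <- which(parts$group == "adolescents")
    adult <- which(parts$group == "adults")
    # align source/target rows by (type, arm)
    key <- paste(parts$type, parts$arm)
    adol_for_child <- adol[match(key[child], key[adol])]
    adult_for_adol <- adult[match(key[adol], key[adult])]
    scit_rows <- lapply(1:3, function(ty) which(parts$arm == paste0("SCIT", ty)))
    cache <<- list(ids = ids, parts = parts, blocks = blocks,
                   child = child, adol = adol, adult = adult,
                   adol_for_child = adol_for_child,
                   adult_for_adol = adult_for_adol,
                   scit_rows = scit_rows,
                   seasonal = parts$type == "seasonal",
                   groups = parts$group)
    cache
  }
})

eng_advance <- function(cohorts, set) {
  ix <- engine_index()
  out <- cohorts
  for (k in names(ix$blocks)) {
    rows <- ix$blocks[[k]]
    out[rows, ] <- cohorts[rows, , drop = FALSE] %*% set[[k]]
  }
  out
}

# Returns list(cohorts, outflow = total persons aged out of 6-65).
eng_age <- function(cohorts) {
  ix <- engine_index()
  mc <- cohorts[ix$child, , drop = FALSE] / 7
  ma <- cohorts[ix$adol, , drop = FALSE] / 6
  mu <- cohorts[ix$adult, , drop = FALSE] / 47
  cohorts[ix$child, ] <- cohorts[ix$child, ] - mc
  cohorts[ix$adol, ] <- cohorts[ix$adol, ] - ma
  cohorts[ix$adult, ] <- cohorts[ix$adult, ] - mu
  cohorts[ix$adol_for_child, ] <- cohorts[ix$adol_for_child, ] + mc
  cohorts[ix$adult_for_adol, ] <- cohorts[ix$adult_for_adol, ] + ma
  list(cohorts = cohorts, outflow = sum(mu))
}

eng_state_cost <- function(cohorts, costs) {
  ix <- engine_index()
  by_group <- rowsum(cohorts[, diseased_states(), drop = FALSE], ix$groups,
                     reorder = FALSE)
  sum(by_group * costs[rownames(by_group), , drop = FALSE])
}

eng_scit_cost <- function(cohorts, schedule) {
  ix <- engine_index()
  alive <- setdiff(disease_states(), "F")
  total <- 0
  for (ty in 1:3) {
    rows <- ix$scit_rows[[ty]]
    if (schedule$mean_mode == "mean") {
      total <- total + sum(cohorts[rows, alive]) * scit_mean_cost(schedule, ty)
    } else {
      seas <- ix$seasonal[rows]
      total <- total +
        sum(cohorts[rows[seas], alive]) * schedule$preseasonal[ty] +
        sum(cohorts[rows[!seas], alive]) * schedule$perennial[ty]
    }
  }
  total
}
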