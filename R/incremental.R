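# Arm-level aggregation and incremental results (the published Tables 3-5
# shapes).

#' Summarize an arm
#'
#' Aggregates per-patient breakdowns into the cost-type decomposition:
#' one-off set-up, ongoing annual fixed, and annual variable totals. Variable
#' costs are the event-driven per-patient costs (everything except the fixed
#' and set-up shares); fixed and set-up totals come from the model inputs for
#' the virtual-ward arm and are zero for standard care. Invariants hold at
#' full precision: population total = set-up + fixed + variable, and
#' per-patient total = population total / cohort size.
#'
#' @param breakdowns Per-patient breakdown data frame from [cost_cohort()].
#' @param inputs A `model_inputs` object.
#' @param arm `"vw"` or `"sc"`.
#' @param scale Annualization factor applied to cohort-level totals and the
#'   cohort size (see [annualize()]); default 1 (already a full-year cohort).
#' @return An object of class `arm_summary`.
#' @export
summarize_arm <- function(breakdowns, inputs, arm = c("vw", "sc"), scale = 1) {
  arm <- match.arg(arm)
  if (!is.data.frame(breakdowns) || nrow(breakdowns) == 0L) {
    stop("breakdowns must be a non-empty per-patient breakdown table")
  }
  stopifnot(inherits(inputs, "model_inputs"), is.finite(scale), scale > 0)
  setup_total <- if (arm == "vw") sum(inputs$setup_costs) else 0
  fixed_total <- if (arm == "vw") sum(inputs$fixed_costs) else 0
  variable_total <- scale * sum(breakdowns$overall -
                                  breakdowns$vw_platform_share -
                                  breakdowns$setup_share)
  cohort_size <- scale * nrow(breakdowns)
  population_total <- setup_total + fixed_total + variable_total
  comp_cols <- c(DIRECT_COMPONENTS, INDIRECT_COMPONENTS)
  structure(
    list(arm = arm,
         setup_total = setup_total,
         fixed_total = fixed_total,
         variable_total = variable_total,
         population_total = population_total,
         per_patient_total = population_total / cohort_size,
         cohort_size = cohort_size,
         component_means = colMeans(breakdowns[, comp_cols, drop = FALSE])),
    class = "arm_summary"
  )
}

#' Incremental result: virtual ward minus standard care
#'
#' Negative values mean the virtual ward saves money relative to standard
#' care. Component deltas (the published per-patient incremental column) are
#' carried when both summaries hold component means.
#'
#' @param vw,sc `arm_summary` objects with equal cohort sizes.
#' @return An object of class `incremental_result`.
#' @export
incremental <- function(vw, sc) {
  stopifnot(inherits(vw, "arm_summary"), inherits(sc, "arm_summary"))
  if (!isTRUE(all.equal(vw$cohort_size, sc$cohort_size))) {
    stop("cohort-size mismatch between arms: ", vw$cohort_size, " vs ",
         sc$cohort_size)
  }
  inc_pop <- vw$population_total - sc$population_total
  structure(
    list(vw = vw, sc = sc,
         incremental_population = inc_pop,
         incremental_per_patient = inc_pop / vw$cohort_size,
         component_deltas = vw$component_means - sc$component_means),
    class = "incremental_result"
  )
}

#' Per-patient component decomposition across arms
#'
#' Mean per-patient cost for every direct and indirect component in each arm
#' plus the incremental column, with direct, indirect and overall total rows.
#' Component deltas sum to the total delta at full precision; rounding to
#' whole pounds happens only in the report writer.
#'
#' @param vw_breakdowns,sc_breakdowns Per-patient breakdown tables from
#'   [cost_cohort()].
#' @return Data frame with columns `component`, `vw`, `sc`, `incremental`.
#' @export
decompose <- function(vw_breakdowns, sc_breakdowns) {
  comp_cols <- c(DIRECT_COMPONENTS, INDIRECT_COMPONENTS)
  vw <- colMeans(vw_breakdowns[, comp_cols, drop = FALSE])
  sc <- colMeans(sc_breakdowns[, comp_cols, drop = FALSE])
  rows <- data.frame(component = comp_cols, vw = unname(vw), sc = unname(sc),
                     stringsAsFactors = FALSE)
  totals <- data.frame(
    component = c("total_direct", "total_indirect", "total"),
    vw = c(sum(vw[DIRECT_COMPONENTS]), sum(vw[INDIRECT_COMPONENTS]), sum(vw)),
    sc = c(sum(sc[DIRECT_COMPONENTS]), sum(sc[INDIRECT_COMPONENTS]), sum(sc)),
    stringsAsFactors = FALSE
  )
  out <- rbind(rows, totals)
  out$incremental <- out$vw - out$sc
  out
}

#' @export
print.arm_summary <- function(x, ...) {
  cat("<arm_summary> arm=", x$arm, " cohort=", format(x$cohort_size), "\n",
      "  setup=", format_gbp(x$setup_total),
      " fixed=", format_gbp(x$fixed_total),
      " variable=", format_gbp(x$variable_total), "\n",
      "  population total=", format_gbp(x$population_total),
      " per patient=", format_gbp(x$per_patient_total), "\n", sep = "")
  invisible(x)
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result> (virtual ward minus standard care)\n",
      "  population: ", format_gbp(x$vw$population_total), " vs ",
      format_gbp(x$sc$population_total), " -> ",
      format_gbp(x$incremental_population), "\n",
      "  per patient: ", format_gbp(x$vw$per_patient_total), " vs ",
      format_gbp(x$sc$per_patient_total), " -> ",
      format_gbp(x$incremental_per_patient), "\n", sep = "")
  invisible(x)
}
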