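# Per-patient cost breakdowns for the virtual-ward arm and the standard-care
# counterfactual.

#' Cost-breakdown component names
#'
#' Direct components are costs the virtual ward itself incurs (platform/fixed
#' share, set-up share, monitoring equipment, point-of-care testing, home
#' visits, home set up, phone/virtual calls). Indirect components are wider
#' system costs within the horizon (outpatient appointments, ED attendances,
#' the initial admission for step-up counterfactuals, readmissions, avoided
#' excess bed days, NHS 111 contacts).
#'
#' @export
DIRECT_COMPONENTS <- c("vw_platform_share", "setup_share", "home_monitoring",
                       "poc_testing", "home_visits", "home_setup", "calls")

#' @rdname DIRECT_COMPONENTS
#' @export
INDIRECT_COMPONENTS <- c("outpatient", "ed_visits", "initial_admission",
                         "readmission", "excess_bed_day_savings", "nhs111")

# counts matrix: patients x EVENT_KINDS, from the long event table
event_counts <- function(cohort) {
  ids <- cohort$patients$id
  m <- matrix(0, nrow = length(ids), ncol = length(EVENT_KINDS),
              dimnames = list(ids, EVENT_KINDS))
  ev <- cohort$events
  if (nrow(ev)) {
    tab <- table(factor(ev$id, levels = ids),
                 factor(ev$kind, levels = EVENT_KINDS))
    m <- m + unclass(tab)
  }
  m
}

#' Per-visit and per-call unit costs implied by the configuration
#'
#' Home visits are priced either from the microcosted activity profile
#' (duration x cost/minute, the default) or from the reference unit cost per
#' visit, per `inputs$visit_costing`. Calls are always microcosted.
#'
#' @param inputs A `model_inputs` object.
#' @return Named vector with `home_visit` and `virtual_call` GBP costs.
#' @export
per_event_staff_costs <- function(inputs) {
  visit <- if (inputs$visit_costing == "reference") {
    unit_amount(inputs, "home_visit")
  } else {
    activity_cost(inputs$activities[["home_visit"]], inputs$staff_roles)
  }
  call <- activity_cost(inputs$activities[["virtual_call"]], inputs$staff_roles)
  c(home_visit = visit, virtual_call = call)
}

#' Cost a cohort of episodes
#'
#' Returns one row per patient with every direct and indirect component plus
#' `direct_total`, `indirect_total` and `overall` (all at full precision;
#' `overall` equals the sum of all components exactly).
#'
#' In the virtual-ward arm, direct costs are the equal per-annualized-patient
#' shares of fixed and set-up costs plus per-event activity and equipment
#' costs; indirect costs are ED attendances, readmissions and NHS 111
#' contacts at unit cost, minus avoided excess bed days for step-down
#' patients; the initial admission and outpatient components are zero by
#' convention. In the standard-care counterfactual all direct components are
#' zero; indirect costs are outpatient, ED, readmission and NHS 111 events at
#' unit cost plus the full admission cost for step-up patients (assumed
#' admitted in the absence of a virtual ward); the avoided-bed-day component
#' is zero (a step-down counterfactual's longer stay appears as the VW arm's
#' negative bed-day component, so published tables reproduce cell-for-cell).
#'
#' @param cohort A `vw_cohort`, already horizon-filtered (see
#'   [apply_horizon()]).
#' @param inputs A `model_inputs` object.
#' @param arm `"vw"` or `"sc"`.
#' @param n_annual Annualized cohort size over which fixed and set-up costs
#'   are shared (VW arm only).
#' @return Data frame of per-patient breakdowns.
#' @export
cost_cohort <- function(cohort, inputs, arm = c("vw", "sc"), n_annual = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(cohort, "vw_cohort"), inherits(inputs, "model_inputs"))
  n <- nrow(cohort$patients)
  if (n == 0L) stop("cannot cost an empty cohort")
  cnt <- event_counts(cohort)
  p <- cohort$patients

  comp <- matrix(0, nrow = n,
                 ncol = length(DIRECT_COMPONENTS) + length(INDIRECT_COMPONENTS),
                 dimnames = list(NULL, c(DIRECT_COMPONENTS, INDIRECT_COMPONENTS)))

  if (arm == "vw") {
    if (is.null(n_annual) || !is.finite(n_annual) || n_annual <= 0) {
      stop("n_annual (> 0) is required to share fixed and set-up costs")
    }
    staff <- per_event_staff_costs(inputs)
    comp[, "vw_platform_share"] <- sum(inputs$fixed_costs) / n_annual
    comp[, "setup_share"] <- sum(inputs$setup_costs) / n_annual
    # equipment costs attach to actual stays: a degenerate zero-stay episode
    # incurs only the shared platform and set-up costs
    onboarded <- as.numeric(p$vw_length_of_stay > 0)
    comp[, "home_monitoring"] <- onboarded * unit_amount(inputs, "home_monitoring")
    comp[, "home_setup"] <- onboarded * unit_amount(inputs, "home_setup")
    comp[, "poc_testing"] <- cnt[, "poc_test"] * unit_amount(inputs, "poc_test")
    comp[, "home_visits"] <-
      (cnt[, "home_visit_routine"] + cnt[, "home_visit_rapid"]) *
      staff[["home_visit"]]
    comp[, "calls"] <- cnt[, "virtual_call"] * staff[["virtual_call"]]
    comp[, "ed_visits"] <- cnt[, "ed_attendance"] * unit_amount(inputs, "ed_attendance")
    comp[, "readmission"] <- cnt[, "readmission"] * unit_amount(inputs, "admission")
    comp[, "nhs111"] <- cnt[, "nhs111_contact"] * unit_amount(inputs, "nhs111_contact")
    comp[, "excess_bed_day_savings"] <-
      -p$bed_days_saved * unit_amount(inputs, "excess_bed_day")
  } else {
    comp[, "outpatient"] <-
      cnt[, "outpatient_appointment"] * unit_amount(inputs, "outpatient_appointment")
    comp[, "ed_visits"] <- cnt[, "ed_attendance"] * unit_amount(inputs, "ed_attendance")
    comp[, "initial_admission"] <-
      (p$pathway == "step_up") * unit_amount(inputs, "admission")
    comp[, "readmission"] <- cnt[, "readmission"] * unit_amount(inputs, "admission")
    comp[, "nhs111"] <- cnt[, "nhs111_contact"] * unit_amount(inputs, "nhs111_contact")
  }

  out <- data.frame(id = p$id, pathway = p$pathway, comp,
                    stringsAsFactors = FALSE)
  out$direct_total <- rowSums(comp[, DIRECT_COMPONENTS, drop = FALSE])
  out$indirect_total <- rowSums(comp[, INDIRECT_COMPONENTS, drop = FALSE])
  out$overall <- out$direct_total + out$indirect_total
  out
}

#' Cost a single virtual-ward episode
#'
#' @param episode A [patient_episode()] (must already be horizon-filtered).
#' @param inputs A `model_inputs` object.
#' @param n_annual Annualized cohort size sharing the fixed and set-up costs.
#' @return One-row breakdown data frame (see [cost_cohort()]).
#' @export
cost_vw_patient <- function(episode, inputs, n_annual) {
  cost_cohort(episode, inputs, arm = "vw", n_annual = n_annual)
}

#' Cost a single standard-care counterfactual episode
#'
#' @param episode A [patient_episode()] carrying counterfactual resource use.
#' @param inputs A `model_inputs` object.
#' @return One-row breakdown data frame (see [cost_cohort()]).
#' @export
cost_sc_patient <- function(episode, inputs) {
  cost_cohort(episode, inputs, arm = "sc")
}
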