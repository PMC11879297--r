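# Deterministic expected-cost model, one-way sensitivity analysis (tornado),
# and break-even threshold analysis.

#' Flatten model inputs into the deterministic parameter vector
#'
#' The scalar parameter space over which one-way sensitivity and break-even
#' analyses operate: unit costs, fixed/set-up totals, annual cohort size, the
#' step-up proportion, and the per-patient event rates of both arms.
#'
#' @param inputs A `model_inputs` object.
#' @return Named numeric vector.
#' @export
model_params <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  cc <- inputs$cohort
  staff <- per_event_staff_costs(inputs)
  n_annual <- round(cc$n_patients * 12 / cc$observed_months)
  c(admission_cost = unit_amount(inputs, "admission"),
    excess_bed_day_cost = unit_amount(inputs, "excess_bed_day"),
    ed_attendance_cost = unit_amount(inputs, "ed_attendance"),
    nhs111_cost = unit_amount(inputs, "nhs111_contact"),
    outpatient_cost = unit_amount(inputs, "outpatient_appointment"),
    poc_test_cost = unit_amount(inputs, "poc_test"),
    home_monitoring_cost = unit_amount(inputs, "home_monitoring"),
    home_setup_cost = unit_amount(inputs, "home_setup"),
    home_visit_cost = unname(staff[["home_visit"]]),
    call_cost = unname(staff[["virtual_call"]]),
    fixed_annual_total = sum(inputs$fixed_costs),
    setup_total = sum(inputs$setup_costs),
    n_annual = n_annual,
    step_up_proportion = cc$step_up_proportion,
    vw_home_visits = cc$vw_rates$home_visits,
    vw_calls = cc$vw_rates$calls,
    vw_poc_tests = cc$vw_rates$poc_tests,
    vw_ed_probability = cc$vw_rates$ed_probability,
    vw_readmission_probability = cc$vw_rates$readmission_probability,
    vw_nhs111_contacts = cc$vw_rates$nhs111_contacts,
    bed_days_saved_step_down = cc$bed_days_saved_step_down,
    sc_outpatient_appointments = cc$sc_rates$outpatient_appointments,
    sc_ed_probability = cc$sc_rates$ed_probability,
    sc_readmission_probability = cc$sc_rates$readmission_probability,
    sc_nhs111_contacts = cc$sc_rates$nhs111_contacts)
}

#' Evaluate the deterministic cost model
#'
#' Expected per-patient and population costs of both arms from rates and
#' unit costs (no Monte-Carlo noise); the evaluation underlying the
#' sensitivity and break-even analyses.
#'
#' @param params Named vector from [model_params()], possibly perturbed.
#' @return List with per-patient arm costs (`vw_pp`, `sc_pp`), the VW
#'   variable (event-driven) per-patient cost `vw_variable_pp`, population
#'   totals, and the incrementals.
#' @export
expected_costs <- function(params) {
  p <- as.list(params)
  vw_variable_pp <- p$home_monitoring_cost + p$home_setup_cost +
    p$vw_poc_tests * p$poc_test_cost +
    p$vw_home_visits * p$home_visit_cost +
    p$vw_calls * p$call_cost +
    p$vw_ed_probability * p$ed_attendance_cost +
    p$vw_readmission_probability * p$admission_cost +
    p$vw_nhs111_contacts * p$nhs111_cost -
    (1 - p$step_up_proportion) * p$bed_days_saved_step_down *
      p$excess_bed_day_cost
  vw_pp <- (p$fixed_annual_total + p$setup_total) / p$n_annual + vw_variable_pp
  sc_pp <- p$sc_outpatient_appointments * p$outpatient_cost +
    p$sc_ed_probability * p$ed_attendance_cost +
    p$step_up_proportion * p$admission_cost +
    p$sc_readmission_probability * p$admission_cost +
    p$sc_nhs111_contacts * p$nhs111_cost
  list(vw_pp = vw_pp, sc_pp = sc_pp, vw_variable_pp = vw_variable_pp,
       vw_population = vw_pp * p$n_annual, sc_population = sc_pp * p$n_annual,
       incremental_pp = vw_pp - sc_pp,
       incremental_population = (vw_pp - sc_pp) * p$n_annual)
}

#' One-way deterministic sensitivity analysis
#'
#' Varies one scalar parameter at a time to `base x (1 - fraction)` and
#' `base x (1 + fraction)` with everything else held at base, re-evaluates
#' the model, and orders results by output spread descending (tornado
#' order), ties broken by parameter label.
#'
#' @param inputs A `model_inputs` object.
#' @param parameters Character vector of parameter labels (names of
#'   [model_params()]); default: every parameter except `n_annual`.
#' @param fraction Variation fraction in (0, 1); default
#'   `inputs$dsa_fraction`.
#' @return Data frame of class `dsa_result`, one row per parameter, columns
#'   `parameter`, `base`, `low`, `high`, `incr_low`, `incr_high`, `spread`,
#'   `sign_flip` (incrementals are per patient). `sign_flip` is `TRUE` iff
#'   the low and high incrementals straddle zero.
#' @export
one_way_dsa <- function(inputs, parameters = NULL,
                        fraction = inputs$dsa_fraction) {
  stopifnot(inherits(inputs, "model_inputs"))
  fraction <- as.numeric(fraction)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  base <- model_params(inputs)
  if (is.null(parameters)) parameters <- setdiff(names(base), "n_annual")
  unknown <- setdiff(parameters, names(base))
  if (length(unknown)) {
    stop("unknown DSA parameter label(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(parameters, function(label) {
    lo <- base; hi <- base
    lo[label] <- base[label] * (1 - fraction)
    hi[label] <- base[label] * (1 + fraction)
    incr_lo <- expected_costs(lo)$incremental_pp
    incr_hi <- expected_costs(hi)$incremental_pp
    data.frame(parameter = label, base = unname(base[label]),
               low = unname(lo[label]), high = unname(hi[label]),
               incr_low = incr_lo, incr_high = incr_hi,
               spread = abs(incr_hi - incr_lo),
               sign_flip = min(incr_lo, incr_hi) < 0 & max(incr_lo, incr_hi) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dsa_result", class(out))
  out
}

#' Break-even threshold analysis
#'
#' The smallest annual patient volume at which the virtual ward's total cost
#' (one-off set-up plus annual fixed plus per-patient variable) no longer
#' exceeds standard care's: the smallest integer `n >= 1` with
#' `setup + fixed + n * vw_variable_pp <= n * sc_pp`, i.e. the ceiling of the
#' fixed-plus-set-up burden over the per-patient net variable saving. If the
#' per-patient saving is non-positive the threshold is unreachable.
#'
#' @param inputs A `model_inputs` object.
#' @return An object of class `breakeven_result`: `threshold` (integer
#'   patients/year, `NA` if unreachable), `per_patient_saving`, `burden`
#'   (fixed + set-up), `reachable`.
#' @export
breakeven <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  params <- model_params(inputs)
  ec <- expected_costs(params)
  saving <- ec$sc_pp - ec$vw_variable_pp
  burden <- unname(params["fixed_annual_total"] + params["setup_total"])
  reachable <- saving > 0
  threshold <- if (reachable) max(1L, as.integer(ceiling(burden / saving))) else NA_integer_
  structure(list(threshold = threshold, per_patient_saving = saving,
                 burden = burden, reachable = reachable),
            class = "breakeven_result")
}

#' @export
print.breakeven_result <- function(x, ...) {
  if (x$reachable) {
    cat("<breakeven_result> threshold: ", x$threshold, " patients/year\n",
        "  fixed+set-up burden ", format_gbp(x$burden),
        ", net variable saving ", format_gbp(x$per_patient_saving),
        " per patient\n", sep = "")
  } else {
    cat("<breakeven_result> unreachable: per-patient net variable saving is",
        "non-positive\n")
  }
  invisible(x)
}
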