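# Priced inputs, currency-year inflation, and configuration ingestion.

#' Unit-cost labels every configuration must price
#'
#' The pathway-costing engine looks these up by label: per-event costs
#' (ED attendance, NHS 111 contact, outpatient appointment, hospital
#' admission, point-of-care test), per-day excess bed day cost, per-patient
#' equipment costs (home monitoring, home set up), and the reference cost of
#' a home visit (the microcosted alternative lives in the activity profiles).
#'
#' @export
REQUIRED_UNIT_COSTS <- c(
  "home_visit", "ed_attendance", "nhs111_contact", "outpatient_appointment",
  "admission", "excess_bed_day", "home_monitoring", "home_setup", "poc_test"
)

#' Create a priced resource
#'
#' A unit cost is a non-negative GBP amount with currency-year provenance.
#' Savings (e.g. avoided excess bed days) are a sign applied at costing time,
#' never stored in the unit cost itself.
#'
#' @param label Unique identifier within a configuration.
#' @param amount Cost in GBP; must be non-negative.
#' @param currency_year Fiscal-year label, e.g. `"2021/22"` (opaque string).
#' @param source Free-text provenance tag.
#' @return An object of class `unit_cost`.
#' @export
unit_cost <- function(label, amount, currency_year = "2021/22", source = "") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  amount <- as.numeric(amount)
  if (length(amount) != 1L || is.na(amount)) {
    stop("unit cost '", label, "': amount must be a single number")
  }
  if (amount < 0) {
    stop("unit cost '", label, "': amount must be >= 0 (got ", amount,
         "); savings are applied at costing time, not stored here")
  }
  structure(
    list(label = label, amount = amount,
         currency_year = as.character(currency_year),
         source = as.character(source)),
    class = "unit_cost"
  )
}

#' Create an inflation index
#'
#' A map of fiscal-year label to a positive index value (e.g. the PSSRU
#' inflation index). Year labels are opaque strings; no date arithmetic is
#' attempted.
#'
#' @param values Named numeric vector, names are fiscal-year labels.
#' @return An object of class `inflation_index`.
#' @export
inflation_index <- function(values) {
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("inflation index values must be named by fiscal-year label")
  }
  values <- vapply(values, as.numeric, numeric(1))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all inflation index values must be positive and finite")
  }
  structure(as.list(values), class = "inflation_index")
}

#' Inflate a cost between fiscal years
#'
#' Multiplies by the ratio of index values: `amount * index[to] / index[from]`.
#'
#' @param amount Cost in GBP.
#' @param from_year,to_year Fiscal-year labels present in `index`.
#' @param index An [inflation_index()].
#' @return The inflated amount (full precision, no rounding).
#' @export
inflate_cost <- function(amount, from_year, to_year, index) {
  stopifnot(inherits(index, "inflation_index"))
  for (yr in c(from_year, to_year)) {
    if (is.null(index[[yr]])) {
      stop("inflation index has no entry for year '", yr, "'")
    }
  }
  amount * index[[to_year]] / index[[from_year]]
}

#' Assemble and validate the full set of model inputs
#'
#' The container every pipeline stage consumes: unit costs, staff roles and
#' activity profiles, fixed annual and one-off set-up cost categories, the
#' cohort parameters (including calibrated event rates), the post-discharge
#' costing horizon, and the one-way sensitivity variation fraction.
#'
#' @param unit_costs List of [unit_cost()] objects (or of plain lists with the
#'   same fields). Labels must be unique and include [REQUIRED_UNIT_COSTS].
#' @param staff_roles Named list of [staff_role()] objects.
#' @param activities Named list of [activity_profile()] objects; must include
#'   `home_visit` and `virtual_call`.
#' @param fixed_costs Named numeric vector of ongoing annual fixed costs
#'   (independent of patient volume), GBP/year.
#' @param setup_costs Named numeric vector of one-off set-up costs, GBP.
#'   Category names must be disjoint from `fixed_costs`.
#' @param cohort A [cohort_config()].
#' @param horizon_days Post-discharge horizon in days; events with day offset
#'   greater than this are considered unrelated to the admission. Default 30.
#' @param dsa_fraction One-way sensitivity variation fraction. Default 0.15.
#' @param visit_costing Either `"microcosted"` (home visits priced from the
#'   `home_visit` activity profile: duration x cost/minute) or `"reference"`
#'   (the national reference unit cost per visit).
#' @param inflation Optional [inflation_index()].
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(unit_costs, staff_roles, activities,
                         fixed_costs, setup_costs, cohort,
                         horizon_days = 30, dsa_fraction = 0.15,
                         visit_costing = c("microcosted", "reference"),
                         inflation = NULL) {
  visit_costing <- match.arg(visit_costing)

  unit_costs <- lapply(unit_costs, function(u) {
    if (inherits(u, "unit_cost")) u
    else unit_cost(u$label, u$amount,
                   u$currency_year %||% "2021/22", u$source %||% "")
  })
  labels <- vapply(unit_costs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate unit cost label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  names(unit_costs) <- labels
  missing <- setdiff(REQUIRED_UNIT_COSTS, labels)
  if (length(missing)) {
    stop("missing required unit cost(s): ", paste(missing, collapse = ", "))
  }

  staff_roles <- lapply(staff_roles, function(r) {
    if (inherits(r, "staff_role")) r
    else staff_role(r$band, r$annual_cost, r$annual_hours)
  })
  names(staff_roles) <- vapply(staff_roles, `[[`, character(1), "band")

  activities <- lapply(activities, function(a) {
    if (inherits(a, "activity_profile")) a
    else activity_profile(a$label, a$duration,
                          mix = a$mix, cost_per_minute = a$cost_per_minute)
  })
  names(activities) <- vapply(activities, `[[`, character(1), "label")
  for (need in c("home_visit", "virtual_call")) {
    if (is.null(activities[[need]])) {
      stop("missing required activity profile: ", need)
    }
  }

  fixed_costs <- unlist(fixed_costs)
  setup_costs <- unlist(setup_costs)
  for (nm in c("fixed_costs", "setup_costs")) {
    v <- get(nm)
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
      stop(nm, " must be a named vector of cost categories")
    }
    if (any(v < 0)) stop(nm, " must be non-negative")
  }
  overlap <- intersect(names(fixed_costs), names(setup_costs))
  if (length(overlap)) {
    stop("cost category in both fixed and set-up buckets: ",
         paste(overlap, collapse = ", "),
         " (a cost appears in exactly one bucket)")
  }

  if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, cohort)

  horizon_days <- as.numeric(horizon_days)
  if (!is.finite(horizon_days) || horizon_days <= 0) {
    stop("horizon_days must be > 0")
  }
  dsa_fraction <- as.numeric(dsa_fraction)
  if (!is.finite(dsa_fraction) || dsa_fraction <= 0 || dsa_fraction >= 1) {
    stop("dsa_fraction must lie strictly between 0 and 1")
  }
  if (!is.null(inflation) && !inherits(inflation, "inflation_index")) {
    inflation <- inflation_index(inflation)
  }

  structure(
    list(unit_costs = unit_costs, staff_roles = staff_roles,
         activities = activities, fixed_costs = fixed_costs,
         setup_costs = setup_costs, cohort = cohort,
         horizon_days = horizon_days, dsa_fraction = dsa_fraction,
         visit_costing = visit_costing, inflation = inflation),
    class = "model_inputs"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up a unit-cost amount by label
#' @param inputs A `model_inputs` object.
#' @param label Unit-cost label.
#' @return The GBP amount.
#' @export
unit_amount <- function(inputs, label) {
  u <- inputs$unit_costs[[label]]
  if (is.null(u)) stop("unknown unit cost label: ", label)
  u$amount
}

CONFIG_SECTIONS <- c("unit_costs", "staff_roles", "activities", "fixed_costs",
                     "setup_costs", "cohort", "horizon_days", "dsa_fraction",
                     "visit_costing", "inflation")

#' Load a model configuration file
#'
#' Reads a JSON configuration with sections `unit_costs`, `staff_roles`,
#' `activities`, `fixed_costs`, `setup_costs`, `cohort` and optional scalars
#' `horizon_days` (default 30), `dsa_fraction` (default 0.15),
#' `visit_costing` and `inflation`. All invariants are enforced; unknown
#' top-level sections are rejected.
#'
#' @param path Path to the configuration file.
#' @return A validated `model_inputs` object.
#' @seealso [default_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("unit_costs", "staff_roles", "activities",
                "fixed_costs", "setup_costs", "cohort")) {
    if (is.null(raw[[key]])) stop("configuration is missing required key: ", key)
  }
  model_inputs(
    unit_costs = raw$unit_costs,
    staff_roles = raw$staff_roles,
    activities = raw$activities,
    fixed_costs = lapply(raw$fixed_costs, as.numeric),
    setup_costs = lapply(raw$setup_costs, as.numeric),
    cohort = rapply(raw$cohort, function(x) x, how = "list"),
    horizon_days = raw$horizon_days %||% 30,
    dsa_fraction = raw$dsa_fraction %||% 0.15,
    visit_costing = raw$visit_costing %||% "microcosted",
    inflation = raw$inflation
  )
}

#' Serialize model inputs back to a configuration file
#'
#' Inverse of [load_config()]: a written configuration reloads to an
#' identical structure (full numeric precision is preserved).
#'
#' @param inputs A `model_inputs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(inputs, path) {
  stopifnot(inherits(inputs, "model_inputs"))
  cfg <- list(
    unit_costs = lapply(unname(inputs$unit_costs), unclass),
    staff_roles = lapply(unname(inputs$staff_roles), unclass),
    activities = lapply(unname(inputs$activities), unclass),
    fixed_costs = as.list(inputs$fixed_costs),
    setup_costs = as.list(inputs$setup_costs),
    cohort = unclass(inputs$cohort),
    horizon_days = inputs$horizon_days,
    dsa_fraction = inputs$dsa_fraction,
    visit_costing = inputs$visit_costing
  )
  if (!is.null(inputs$inflation)) cfg$inflation <- unclass(inputs$inflation)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Path to the shipped default configuration
#'
#' The default reproduces the published heart-failure virtual-ward inputs:
#' NHS reference unit costs (admission 2587, excess bed day 338, ED 158,
#' NHS 111 contact 11, outpatient 213, home visit 102), the microcosted
#' activity profiles (45 min at 1.02 GBP/min; 10 min at 1.79 GBP/min),
#' aggregate fixed (308 113) and set-up (4685) costs, and event rates
#' calibrated to the published per-patient component costs.
#'
#' @return File path within the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "hf_vw_default.json", package = "vwcost",
              mustWork = TRUE)
}

#' Construct the default model inputs in code
#'
#' Identical to `load_config(default_config_path())`; see
#' [default_config_path()] for what the defaults encode. Event rates are
#' derived with [calibrate_rates()] from the published per-patient component
#' costs and the unit costs.
#'
#' @return A `model_inputs` object.
#' @export
default_config <- function() {
  ucs <- list(
    unit_cost("home_visit", 102, "2021/22", "NHS Cost Collection"),
    unit_cost("ed_attendance", 158, "2021/22", "NHS Cost Collection"),
    unit_cost("nhs111_contact", 11, "2021/22", "literature"),
    unit_cost("outpatient_appointment", 213, "2021/22", "NHS Cost Collection"),
    unit_cost("admission", 2587, "2021/22",
              "NHS Cost Collection, NEL short+long stay, HF/shock HRGs"),
    unit_cost("excess_bed_day", 338, "2021/22",
              "NHS Cost Collection 2017/18 inflated via PSSRU index"),
    unit_cost("home_monitoring", 34, "2021/22", "service records"),
    unit_cost("home_setup", 30, "2021/22", "service records"),
    unit_cost("poc_test", 24.50, "2021/22",
              "package estimate: iSTAT cartridge + handling (synthetic)")
  )
  roles <- list(
    staff_role("nurse_band6", annual_cost = 94733, annual_hours = 1553),
    staff_role("consultant", annual_cost = 274176, annual_hours = 2142)
  )
  acts <- list(
    activity_profile("home_visit", duration = 45, cost_per_minute = 1.02),
    activity_profile("virtual_call", duration = 10, cost_per_minute = 1.79)
  )
  visit_cost <- 45 * 1.02   # microcosted home visit
  call_cost <- 10 * 1.79
  vw_rates <- calibrate_rates(
    c(home_visits = 154, calls = 140, poc_tests = 98,
      ed_probability = 14, readmission_probability = 326,
      nhs111_contacts = 1),
    c(home_visits = visit_cost, calls = call_cost, poc_tests = 24.50,
      ed_probability = 158, readmission_probability = 2587,
      nhs111_contacts = 11)
  )
  step_up <- 1164 / 2587    # implied by initial-admission component
  # 558 GBP of bed-day savings per patient over all patients -> per step-down
  bed_days <- calibrate_rates(c(bed_days = 558), c(bed_days = 338)) /
    (1 - step_up)
  sc_rates <- calibrate_rates(
    c(outpatient_appointments = 117, ed_probability = 19,
      readmission_probability = 556, nhs111_contacts = 1),
    c(outpatient_appointments = 213, ed_probability = 158,
      readmission_probability = 2587, nhs111_contacts = 11)
  )
  cohort <- cohort_config(
    n_patients = 324, observed_months = 6,
    step_up_proportion = step_up,
    age = list(mean = 78, sd = 10, min = 40, max = 100),
    p_female = 0.45,
    diagnosis = list(codes = c("I50.0", "I50.1", "I50.9"),
                     weights = c(0.25, 0.15, 0.60)),
    vw_rates = as.list(vw_rates),
    sc_rates = as.list(sc_rates),
    bed_days_saved_step_down = unname(bed_days),
    mean_vw_length_of_stay = 7,
    rapid_visit_proportion = 0.2,
    event_day_max = 45,
    control_multiplier = 2,
    control_age_shift = 2
  )
  model_inputs(
    unit_costs = ucs, staff_roles = roles, activities = acts,
    fixed_costs = c(vw_running_aggregate = 308113),
    setup_costs = c(communications = 4685),
    cohort = cohort,
    horizon_days = 30, dsa_fraction = 0.15,
    visit_costing = "microcosted"
  )
}
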