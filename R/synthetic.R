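# Synthetic virtual-ward cohorts and control pools with the statistical
# structure the analysis assumes, calibrated so expected per-patient component
# costs match published figures.

#' Cohort-generation parameters
#'
#' Event rates are defined as expected counts (or probabilities, for binary
#' events) **within the costing horizon**: that is what published per-patient
#' component costs measure. The generator also scatters events beyond the
#' horizon (up to `event_day_max`) so horizon filtering is exercised; drawn
#' totals are inflated accordingly, so within-horizon rates converge to the
#' configured values.
#'
#' @param n_patients Number of patients observed (> 0).
#' @param observed_months Observation window in months, in (0, 12].
#' @param step_up_proportion Probability a patient is step-up (admission
#'   avoidance) rather than step-down (early supported discharge).
#' @param age List `mean`, `sd`, `min`, `max`: truncated-normal age
#'   distribution in years.
#' @param p_female Probability of gender `"F"`.
#' @param diagnosis List `codes` (ICD-10 strings) and `weights`.
#' @param vw_rates List of per-patient 30-day means for the virtual-ward arm:
#'   `home_visits`, `calls`, `poc_tests` and `nhs111_contacts` (count means),
#'   `ed_probability` and `readmission_probability` (binary probabilities).
#' @param sc_rates List for the standard-care counterfactual:
#'   `outpatient_appointments`, `nhs111_contacts` (count means),
#'   `ed_probability`, `readmission_probability`.
#' @param bed_days_saved_step_down Mean avoided hospital bed days per
#'   step-down patient.
#' @param mean_vw_length_of_stay Mean days on the virtual ward.
#' @param rapid_visit_proportion Share of home visits that are rapid-response
#'   rather than routine (both are costed identically).
#' @param event_day_max Latest possible event day offset; days beyond the
#'   horizon exist so the horizon filter has work to do.
#' @param control_multiplier Control-pool size as a multiple (>= 2
#'   recommended) of the treated cohort.
#' @param control_age_shift Years added to the control pool's mean age, so
#'   matching has signal to remove.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, observed_months, step_up_proportion,
                          age = list(mean = 78, sd = 10, min = 40, max = 100),
                          p_female = 0.45,
                          diagnosis = list(codes = c("I50.0", "I50.1", "I50.9"),
                                           weights = c(0.25, 0.15, 0.60)),
                          vw_rates, sc_rates, bed_days_saved_step_down,
                          mean_vw_length_of_stay = 7,
                          rapid_visit_proportion = 0.2,
                          event_day_max = 45,
                          control_multiplier = 2,
                          control_age_shift = 2) {
  n_patients <- as.integer(n_patients)
  if (!is.finite(n_patients) || n_patients <= 0L) stop("n_patients must be > 0")
  observed_months <- as.numeric(observed_months)
  if (!is.finite(observed_months) || observed_months <= 0 ||
      observed_months > 12) {
    stop("observed_months must lie in (0, 12]")
  }
  probs <- c(step_up_proportion = step_up_proportion, p_female = p_female,
             rapid_visit_proportion = rapid_visit_proportion,
             vw_ed = vw_rates$ed_probability,
             vw_readmission = vw_rates$readmission_probability,
             sc_ed = sc_rates$ed_probability,
             sc_readmission = sc_rates$readmission_probability)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  rates <- c(unlist(vw_rates), unlist(sc_rates),
             bed_days_saved = bed_days_saved_step_down,
             mean_los = mean_vw_length_of_stay)
  if (any(rates < 0)) stop("all rate means must be >= 0")
  need_vw <- c("home_visits", "calls", "poc_tests", "ed_probability",
               "readmission_probability", "nhs111_contacts")
  need_sc <- c("outpatient_appointments", "ed_probability",
               "readmission_probability", "nhs111_contacts")
  if (length(setdiff(need_vw, names(vw_rates)))) {
    stop("vw_rates is missing: ",
         paste(setdiff(need_vw, names(vw_rates)), collapse = ", "))
  }
  if (length(setdiff(need_sc, names(sc_rates)))) {
    stop("sc_rates is missing: ",
         paste(setdiff(need_sc, names(sc_rates)), collapse = ", "))
  }
  if (length(diagnosis$codes) != length(diagnosis$weights) ||
      any(unlist(diagnosis$weights) < 0)) {
    stop("diagnosis codes and weights must align, weights >= 0")
  }
  if (event_day_max < 0) stop("event_day_max must be >= 0")
  if (control_multiplier < 1) stop("control_multiplier must be >= 1")
  structure(
    list(n_patients = n_patients, observed_months = observed_months,
         step_up_proportion = as.numeric(step_up_proportion),
         age = lapply(age, as.numeric), p_female = as.numeric(p_female),
         diagnosis = list(codes = as.character(unlist(diagnosis$codes)),
                          weights = as.numeric(unlist(diagnosis$weights))),
         vw_rates = lapply(vw_rates[need_vw], as.numeric),
         sc_rates = lapply(sc_rates[need_sc], as.numeric),
         bed_days_saved_step_down = as.numeric(bed_days_saved_step_down),
         mean_vw_length_of_stay = as.numeric(mean_vw_length_of_stay),
         rapid_visit_proportion = as.numeric(rapid_visit_proportion),
         event_day_max = as.numeric(event_day_max),
         control_multiplier = as.numeric(control_multiplier),
         control_age_shift = as.numeric(control_age_shift)),
    class = "cohort_config"
  )
}

#' Back-derive event rates from per-patient component costs
#'
#' For a component whose cost is `rate x unit cost`, the implied rate is the
#' target per-patient component cost divided by the unit cost (e.g. a
#' readmission component of 326 GBP at an admission cost of 2587 GBP implies
#' a 30-day readmission probability of 0.126).
#'
#' @param targets Named numeric vector of per-patient component costs (GBP).
#' @param unit_costs Named numeric vector of unit costs, same names.
#' @return Named numeric vector of implied rates.
#' @export
calibrate_rates <- function(targets, unit_costs) {
  targets <- unlist(targets)
  unit_costs <- unlist(unit_costs)
  missing <- setdiff(names(targets), names(unit_costs))
  if (length(missing)) {
    stop("no unit cost supplied for target(s): ", paste(missing, collapse = ", "))
  }
  unit_costs <- unit_costs[names(targets)]
  if (any(unit_costs <= 0)) {
    stop("unit costs must be > 0 to calibrate: ",
         paste(names(unit_costs)[unit_costs <= 0], collapse = ", "))
  }
  targets / unit_costs
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# events for one kind: count per patient (Poisson at mean, or Bernoulli at
# probability), day offsets uniform on 0..day_max. `inflate` rescales the
# drawn mean so the expected within-horizon count equals the configured rate.
draw_events <- function(ids, kind, rate, day_max, inflate, binary = FALSE) {
  n <- length(ids)
  if (binary) {
    p <- rate * inflate
    if (p > 1) {
      warning("inflated probability for '", kind, "' capped at 1")
      p <- 1
    }
    k <- stats::rbinom(n, 1L, p)
  } else {
    k <- stats::rpois(n, rate * inflate)
  }
  total <- sum(k)
  if (!total) {
    return(data.frame(id = character(), kind = character(), day = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = rep(ids, k), kind = kind,
             day = sample.int(day_max + 1L, total, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic virtual-ward cohort and control pool
#'
#' Reproducible given `seed`. Event days are uniform on `0..event_day_max`
#' (so some fall beyond the horizon and are later filtered); drawn counts are
#' inflated by `(event_day_max + 1) / (horizon + 1)` so that within-horizon
#' event rates converge to the configured ones. The control pool shares the
#' treated covariate distribution apart from a configurable age shift, and
#' carries counterfactual (standard-care) resource use drawn from `sc_rates`.
#'
#' @param inputs A `model_inputs` object (its `cohort` and `horizon_days` are
#'   used) or a bare [cohort_config()].
#' @param seed Integer seed; mandatory for reproducibility.
#' @param horizon Costing horizon in days; defaults to the model inputs'
#'   horizon (30 when a bare `cohort_config` is given).
#' @return An object of class `synthetic_cohorts`: `vw` (a [vw_cohort()]) and
#'   `controls` (list with covariate table `patients` and `events`).
#' @export
generate_cohort <- function(inputs, seed, horizon = NULL) {
  if (inherits(inputs, "model_inputs")) {
    cc <- inputs$cohort
    if (is.null(horizon)) horizon <- inputs$horizon_days
  } else if (inherits(inputs, "cohort_config")) {
    cc <- inputs
    if (is.null(horizon)) horizon <- 30
  } else {
    stop("inputs must be a model_inputs or cohort_config object")
  }
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is required")
  set.seed(as.integer(seed))

  n <- cc$n_patients
  ids <- sprintf("VW%05d", seq_len(n))
  pathway <- ifelse(stats::rbinom(n, 1L, cc$step_up_proportion) == 1L,
                    "step_up", "step_down")
  age <- rtrunc_norm(n, cc$age$mean, cc$age$sd, cc$age$min, cc$age$max)
  gender <- ifelse(stats::rbinom(n, 1L, cc$p_female) == 1L, "F", "M")
  w <- cc$diagnosis$weights / sum(cc$diagnosis$weights)
  icd10 <- sample(cc$diagnosis$codes, n, replace = TRUE, prob = w)
  # every admission lasts at least one day (so each patient is onboarded and
  # incurs the monitoring and home set-up equipment costs exactly once)
  los <- 1L + stats::rpois(n, max(cc$mean_vw_length_of_stay - 1, 0))
  bds <- ifelse(pathway == "step_down",
                stats::rpois(n, cc$bed_days_saved_step_down), 0L)

  day_max <- cc$event_day_max
  inflate <- (day_max + 1) / (min(day_max, horizon) + 1)

  visits <- draw_events(ids, "home_visit_routine", cc$vw_rates$home_visits,
                        day_max, inflate)
  if (nrow(visits)) {
    rapid <- stats::rbinom(nrow(visits), 1L, cc$rapid_visit_proportion) == 1L
    visits$kind[rapid] <- "home_visit_rapid"
  }
  vw_events <- rbind(
    visits,
    draw_events(ids, "virtual_call", cc$vw_rates$calls, day_max, inflate),
    draw_events(ids, "poc_test", cc$vw_rates$poc_tests, day_max, inflate),
    draw_events(ids, "nhs111_contact", cc$vw_rates$nhs111_contacts,
                day_max, inflate),
    draw_events(ids, "ed_attendance", cc$vw_rates$ed_probability,
                day_max, inflate, binary = TRUE),
    draw_events(ids, "readmission", cc$vw_rates$readmission_probability,
                day_max, inflate, binary = TRUE)
  )
  vw <- vw_cohort(
    data.frame(id = ids, pathway = pathway, age = age, gender = gender,
               icd10 = icd10, vw_length_of_stay = los, bed_days_saved = bds,
               stringsAsFactors = FALSE),
    vw_events
  )

  m <- as.integer(ceiling(cc$control_multiplier * n))
  c_ids <- sprintf("SC%05d", seq_len(m))
  controls <- data.frame(
    id = c_ids,
    age = rtrunc_norm(m, cc$age$mean + cc$control_age_shift, cc$age$sd,
                      cc$age$min, cc$age$max),
    gender = ifelse(stats::rbinom(m, 1L, cc$p_female) == 1L, "F", "M"),
    icd10 = sample(cc$diagnosis$codes, m, replace = TRUE, prob = w),
    stringsAsFactors = FALSE
  )
  sc_events <- rbind(
    draw_events(c_ids, "outpatient_appointment",
                cc$sc_rates$outpatient_appointments, day_max, inflate),
    draw_events(c_ids, "nhs111_contact", cc$sc_rates$nhs111_contacts,
                day_max, inflate),
    draw_events(c_ids, "ed_attendance", cc$sc_rates$ed_probability,
                day_max, inflate, binary = TRUE),
    draw_events(c_ids, "readmission", cc$sc_rates$readmission_probability,
                day_max, inflate, binary = TRUE)
  )
  structure(
    list(vw = vw,
         controls = list(patients = controls, events = sc_events)),
    class = "synthetic_cohorts"
  )
}

#' Build the standard-care arm from matched controls
#'
#' Each matched control contributes its (counterfactual) resource use, costed
#' under the treated partner's pathway label: a step-up patient's
#' counterfactual includes the initial hospital admission, a step-down
#' patient's does not (their longer stay is the VW arm's negative
#' excess-bed-day component). Avoided bed days are zero by convention in this
#' arm.
#'
#' @param match A `match_result` from [match_1to1()].
#' @param vw The treated [vw_cohort()].
#' @param controls The control pool (list with `patients`, `events`).
#' @return A [vw_cohort()] for the standard-care arm, ordered like `match$pairs`.
#' @export
build_sc_arm <- function(match, vw, controls) {
  stopifnot(inherits(match, "match_result"))
  pairs <- match$pairs
  if (!nrow(pairs)) stop("no matched pairs: cannot build the standard-care arm")
  ci <- match(pairs$control_id, controls$patients$id)
  ti <- match(pairs$treated_id, vw$patients$id)
  patients <- data.frame(
    id = controls$patients$id[ci],
    pathway = vw$patients$pathway[ti],
    age = controls$patients$age[ci],
    gender = controls$patients$gender[ci],
    icd10 = controls$patients$icd10[ci],
    vw_length_of_stay = 0,
    bed_days_saved = 0,
    stringsAsFactors = FALSE
  )
  events <- controls$events[controls$events$id %in% patients$id, , drop = FALSE]
  vw_cohort(patients, events)
}
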