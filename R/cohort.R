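# Patient-level containers, the post-discharge horizon, and annualization.

#' Recognized resource-use event kinds
#' @export
EVENT_KINDS <- c("home_visit_routine", "home_visit_rapid", "virtual_call",
                 "poc_test", "ed_attendance", "readmission", "nhs111_contact",
                 "outpatient_appointment")

PATIENT_COLS <- c("id", "pathway", "age", "gender", "icd10",
                  "vw_length_of_stay", "bed_days_saved")

#' Build a patient cohort
#'
#' The unit of analysis: one row per patient plus a long-format event table
#' (id, kind, day offset from discharge; day 0 is the day of discharge).
#' Invariants enforced: pathway is step_up or step_down; bed days saved are
#' non-negative and zero for step-up patients (avoided bed days only arise
#' from early supported discharge); day offsets and lengths of stay are
#' non-negative; event kinds are drawn from [EVENT_KINDS].
#'
#' @param patients Data frame with columns `id`, `pathway`
#'   (`"step_up"`/`"step_down"`), `age`, `gender` (`"F"`/`"M"`), `icd10`,
#'   `vw_length_of_stay`, `bed_days_saved`.
#' @param events Data frame with columns `id`, `kind`, `day`.
#' @return An object of class `vw_cohort`.
#' @export
vw_cohort <- function(patients,
                      events = data.frame(id = character(), kind = character(),
                                          day = integer())) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  missing <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing)) {
    stop("patient table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(patients$id)) stop("patient ids must be unique")
  if (!all(patients$pathway %in% c("step_up", "step_down"))) {
    stop("pathway must be 'step_up' or 'step_down'")
  }
  if (any(patients$bed_days_saved < 0)) stop("bed_days_saved must be >= 0")
  bad <- patients$pathway == "step_up" & patients$bed_days_saved != 0
  if (any(bad)) {
    stop("bed_days_saved must be 0 for step-up patients (ids: ",
         paste(utils::head(patients$id[bad], 5), collapse = ", "), ")")
  }
  if (any(patients$vw_length_of_stay < 0)) stop("vw_length_of_stay must be >= 0")
  if (nrow(events)) {
    missing <- setdiff(c("id", "kind", "day"), names(events))
    if (length(missing)) {
      stop("event table is missing column(s): ", paste(missing, collapse = ", "))
    }
    unknown <- setdiff(unique(events$kind), EVENT_KINDS)
    if (length(unknown)) {
      stop("unknown event kind(s): ", paste(unknown, collapse = ", "))
    }
    if (any(events$day < 0)) stop("event day offsets must be >= 0")
    orphan <- setdiff(unique(events$id), patients$id)
    if (length(orphan)) {
      stop("events reference unknown patient id(s): ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  structure(list(patients = patients, events = events), class = "vw_cohort")
}

#' Build a single patient episode
#'
#' Convenience constructor for a one-patient cohort; the per-patient costing
#' functions accept these directly.
#'
#' @param id Patient identifier.
#' @param pathway `"step_up"` (admission avoidance) or `"step_down"`
#'   (early supported discharge).
#' @param age,gender,icd10 Covariates used for propensity matching.
#' @param vw_length_of_stay Days on the virtual ward.
#' @param bed_days_saved Avoided hospital bed days (step-down only).
#' @param events Data frame with columns `kind`, `day`.
#' @return An object of class `patient_episode` (also a one-row `vw_cohort`).
#' @export
patient_episode <- function(id, pathway, age = NA_real_, gender = NA_character_,
                            icd10 = NA_character_, vw_length_of_stay = 0,
                            bed_days_saved = 0,
                            events = data.frame(kind = character(),
                                                day = integer())) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) events$id <- id
  co <- vw_cohort(
    data.frame(id = id, pathway = pathway, age = age, gender = gender,
               icd10 = icd10, vw_length_of_stay = vw_length_of_stay,
               bed_days_saved = bed_days_saved, stringsAsFactors = FALSE),
    events
  )
  class(co) <- c("patient_episode", class(co))
  co
}

#' Apply the post-discharge costing horizon
#'
#' Removes events with day offset strictly greater than `horizon`; resource
#' use beyond the horizon is assumed unrelated to the admission. The boundary
#' is inclusive (an event on day 30 falls inside a 30-day horizon) and the
#' operation is idempotent.
#'
#' @param cohort A `vw_cohort` (or `patient_episode`).
#' @param horizon Days (> 0), default 30.
#' @return The filtered cohort; all other fields unchanged.
#' @export
apply_horizon <- function(cohort, horizon = 30) {
  stopifnot(inherits(cohort, "vw_cohort"))
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  cohort$events <- cohort$events[cohort$events$day <= horizon, , drop = FALSE]
  rownames(cohort$events) <- NULL
  cohort
}

#' Annualization factor for a part-year observation window
#'
#' Cohort-level totals (costs, event counts, patient numbers) multiply by
#' `12 / observed_months`; patient-level records are never duplicated.
#'
#' @param cohort A `vw_cohort`.
#' @param observed_months Observation window in months, in (0, 12].
#' @return List with `factor` (the scale factor) and `n_annual`
#'   (the extrapolated annual cohort size, rounded to the nearest patient).
#' @export
annualize <- function(cohort, observed_months) {
  stopifnot(inherits(cohort, "vw_cohort"))
  observed_months <- as.numeric(observed_months)
  if (!is.finite(observed_months) || observed_months <= 0 ||
      observed_months > 12) {
    stop("observed_months must lie in (0, 12]")
  }
  factor <- 12 / observed_months
  list(factor = factor,
       n_annual = as.integer(round(nrow(cohort$patients) * factor)))
}

#' @export
print.vw_cohort <- function(x, ...) {
  cat("<vw_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$events), " events\n", sep = "")
  if (nrow(x$patients)) {
    tab <- table(x$patients$pathway)
    cat("  pathway: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
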