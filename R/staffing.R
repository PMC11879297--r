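# Staff cost per minute and microcosting of timed activities.

#' Define a staff role
#'
#' The annual total employment cost should include wages/salary, oncosts,
#' qualifications, training and overheads (the PSSRU "total cost per year"
#' convention), so the derived per-minute rate is overhead-inclusive.
#'
#' @param band Band label, e.g. `"nurse_band6"`.
#' @param annual_cost Total employment cost, GBP/year (>= 0).
#' @param annual_hours Annual working hours (> 0); PSSRU uses 1553 for an
#'   average nurse and 2142 for a consultant.
#' @return An object of class `staff_role`.
#' @export
staff_role <- function(band, annual_cost, annual_hours) {
  stopifnot(is.character(band), length(band) == 1L, nzchar(band))
  annual_cost <- as.numeric(annual_cost)
  annual_hours <- as.numeric(annual_hours)
  if (!is.finite(annual_cost) || annual_cost < 0) {
    stop("staff role '", band, "': annual cost must be >= 0")
  }
  if (!is.finite(annual_hours) || annual_hours <= 0) {
    stop("staff role '", band, "': annual working hours must be > 0")
  }
  structure(list(band = band, annual_cost = annual_cost,
                 annual_hours = annual_hours),
            class = "staff_role")
}

#' Staff cost per minute
#'
#' Annual employment cost divided by annual working minutes.
#'
#' @param role A [staff_role()].
#' @return GBP per minute.
#' @export
cost_per_minute <- function(role) {
  stopifnot(inherits(role, "staff_role"))
  role$annual_cost / (role$annual_hours * 60)
}

#' Define a timed activity performed by a staff mix
#'
#' Either a staff `mix` (role -> proportion, proportions summing to 1) or a
#' blended `cost_per_minute` override must be supplied. The override exists
#' because published sources often state a blended rate (e.g. "Bands 5 or 7,
#' 1.02 GBP/min") without the underlying proportions.
#'
#' @param label Activity label.
#' @param duration Minutes (> 0).
#' @param mix Optional named numeric vector/list of role proportions.
#' @param cost_per_minute Optional blended GBP/minute override.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(label, duration, mix = NULL,
                             cost_per_minute = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0) {
    stop("activity '", label, "': duration must be > 0 minutes")
  }
  if (!is.null(mix)) {
    mix <- unlist(mix)
    if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
      stop("activity '", label, "': staff mix must be named by role")
    }
    if (any(mix < 0)) stop("activity '", label, "': mix proportions must be >= 0")
    if (abs(sum(mix) - 1) > 1e-9) {
      stop("activity '", label, "': mix proportions must sum to 1 (got ",
           format(sum(mix)), ")")
    }
  }
  if (!is.null(cost_per_minute)) {
    cost_per_minute <- as.numeric(cost_per_minute)
    if (!is.finite(cost_per_minute) || cost_per_minute < 0) {
      stop("activity '", label, "': override cost per minute must be >= 0")
    }
  }
  if (is.null(mix) && is.null(cost_per_minute)) {
    stop("activity '", label, "': supply a staff mix or a cost-per-minute override")
  }
  structure(list(label = label, duration = duration,
                 mix = if (is.null(mix)) NULL else as.list(mix),
                 cost_per_minute = cost_per_minute),
            class = "activity_profile")
}

#' Cost a timed activity
#'
#' `duration x rate`, where the rate is the override if set, else the
#' mix-weighted average of the roles' [cost_per_minute()].
#'
#' @param profile An [activity_profile()].
#' @param roles Named list of [staff_role()] objects (only needed when the
#'   profile carries a staff mix rather than an override).
#' @return GBP per performed activity.
#' @export
activity_cost <- function(profile, roles = list()) {
  stopifnot(inherits(profile, "activity_profile"))
  if (!is.null(profile$cost_per_minute)) {
    return(profile$duration * profile$cost_per_minute)
  }
  mix <- unlist(profile$mix)
  rate <- 0
  for (band in names(mix)) {
    role <- roles[[band]]
    if (is.null(role)) {
      stop("activity '", profile$label, "': staff mix names role '", band,
           "' which is not defined, and no override cost per minute is set")
    }
    rate <- rate + mix[[band]] * cost_per_minute(role)
  }
  profile$duration * rate
}
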