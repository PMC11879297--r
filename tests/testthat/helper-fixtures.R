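# Fixtures built in code.

# published per-patient component costs (printed table inputs for identity and
# calibration checks)
printed_components <- function() {
  list(
    vw_direct = c(vw_platform_share = 475, setup_share = 7,
                  home_monitoring = 34, poc_testing = 98, home_visits = 154,
                  home_setup = 30, calls = 140),
    vw_indirect = c(outpatient = 0, ed_visits = 14, initial_admission = 0,
                    readmission = 326, excess_bed_day_savings = -558,
                    nhs111 = 1),
    sc_indirect = c(outpatient = 117, ed_visits = 19, initial_admission = 1164,
                    readmission = 556, excess_bed_day_savings = 0, nhs111 = 1),
    totals = list(vw_population = 467524, sc_population = 1203036,
                  incremental_population = -735512,
                  vw_per_patient = 721, sc_per_patient = 1857,
                  incremental_per_patient = -1135,
                  vw_direct = 939, vw_indirect_total = -218,
                  sc_indirect_total = 1857,
                  incremental_indirect_total = -2074,
                  setup = 4685, fixed = 308113, vw_variable = 154727,
                  cohort = 648)
  )
}

# a one-row per-patient breakdown frame with prescribed component values
breakdown_row <- function(direct = NULL, indirect = NULL, id = "P1",
                          pathway = "step_down") {
  comp <- stats::setNames(numeric(length(DIRECT_COMPONENTS) +
                                    length(INDIRECT_COMPONENTS)),
                          c(DIRECT_COMPONENTS, INDIRECT_COMPONENTS))
  comp[names(direct)] <- direct
  comp[names(indirect)] <- indirect
  out <- data.frame(id = id, pathway = pathway, t(comp),
                    stringsAsFactors = FALSE)
  out$direct_total <- sum(comp[DIRECT_COMPONENTS])
  out$indirect_total <- sum(comp[INDIRECT_COMPONENTS])
  out$overall <- out$direct_total + out$indirect_total
  out
}

# a small random episode cohort exercising every event kind
random_cohort <- function(n = 25, seed = 42, day_max = 45) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  pathway <- sample(c("step_up", "step_down"), n, replace = TRUE)
  patients <- data.frame(
    id = ids, pathway = pathway,
    age = round(runif(n, 45, 95)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    icd10 = sample(c("I50.0", "I50.9"), n, replace = TRUE),
    vw_length_of_stay = 1 + rpois(n, 5),
    bed_days_saved = ifelse(pathway == "step_down", rpois(n, 3), 0),
    stringsAsFactors = FALSE
  )
  k <- rpois(n, 4)
  events <- data.frame(
    id = rep(ids, k),
    kind = sample(EVENT_KINDS, sum(k), replace = TRUE),
    day = sample(0:day_max, sum(k), replace = TRUE),
    stringsAsFactors = FALSE
  )
  vw_cohort(patients, events)
}

# random covariate pools with overlapping distributions
random_pools <- function(n_t = 40, n_c = 80, age_shift = 2, seed = 1) {
  set.seed(seed)
  treated <- data.frame(
    id = sprintf("T%03d", seq_len(n_t)),
    age = rnorm(n_t, 76, 9),
    gender = sample(c("F", "M"), n_t, replace = TRUE),
    icd10 = sample(c("I50.0", "I50.1", "I50.9"), n_t, replace = TRUE),
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    id = sprintf("C%03d", seq_len(n_c)),
    age = rnorm(n_c, 76 + age_shift, 9),
    gender = sample(c("F", "M"), n_c, replace = TRUE),
    icd10 = sample(c("I50.0", "I50.1", "I50.9"), n_c, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(treated = treated, controls = controls)
}

# default inputs with randomly jittered scalars (for break-even properties);
# some draws make the virtual ward non-saving on purpose
jittered_inputs <- function(base = default_config()) {
  inputs <- base
  for (lbl in names(inputs$unit_costs)) {
    inputs$unit_costs[[lbl]]$amount <-
      inputs$unit_costs[[lbl]]$amount * runif(1, 0.3, 3)
  }
  inputs$fixed_costs[] <- inputs$fixed_costs * runif(1, 0.05, 4)
  inputs$setup_costs[] <- inputs$setup_costs * runif(1, 0.05, 4)
  for (r in names(inputs$cohort$vw_rates)) {
    inputs$cohort$vw_rates[[r]] <- inputs$cohort$vw_rates[[r]] * runif(1, 0, 3)
  }
  for (r in names(inputs$cohort$sc_rates)) {
    inputs$cohort$sc_rates[[r]] <- inputs$cohort$sc_rates[[r]] * runif(1, 0, 3)
  }
  inputs$cohort$bed_days_saved_step_down <-
    inputs$cohort$bed_days_saved_step_down * runif(1, 0, 3)
  inputs$cohort$step_up_proportion <- runif(1)
  inputs
}

# temporary config file with selected fields modified at the raw-JSON level
config_variant <- function(modify = identity, .env = parent.frame()) {
  raw <- jsonlite::read_json(default_config_path(), simplifyVector = FALSE)
  raw <- modify(raw)
  path <- withr::local_tempfile(fileext = ".json", .local_envir = .env)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}
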