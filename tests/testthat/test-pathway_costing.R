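inputs <- default_config()

test_that("the 30-day horizon is inclusive and idempotent", {
  ep <- patient_episode("P1", "step_down",
                        events = data.frame(kind = "virtual_call",
                                            day = c(5, 30, 31)))
  out <- apply_horizon(ep, 30)
  expect_equal(sort(out$events$day), c(5, 30))
  expect_identical(apply_horizon(out, 30)$events, out$events)

  empty <- patient_episode("P2", "step_up")
  expect_identical(apply_horizon(empty, 30)$events, empty$events)
})

test_that("horizon filtering agrees with the brute-force event filter", {
  co <- random_cohort(n = 100, seed = 11)
  kept <- apply_horizon(co, 30)$events
  brute <- oracle_horizon_keep(co$events, 30)
  expect_equal(nrow(kept), nrow(brute))
  expect_equal(nrow(kept), sum(co$events$day <= 30))
  sorted <- function(df) {
    df <- df[order(df$id, df$kind, df$day), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(sorted(kept), sorted(brute), ignore_attr = TRUE)
  expect_error(apply_horizon(co, 0), "> 0")
})

test_that("annualization scales cohorts without duplicating records", {
  co <- random_cohort(n = 324, seed = 3)
  ann <- annualize(co, 6)
  expect_equal(ann$factor, 2.0)
  expect_equal(ann$n_annual, 648L)
  expect_equal(annualize(co, 12)$factor, 1.0)
  expect_error(annualize(co, 0), "0, 12")
  expect_error(annualize(co, 12.5), "0, 12")
})

test_that("cohort invariants are enforced at construction", {
  base <- data.frame(id = "A", pathway = "step_up", age = 80, gender = "F",
                     icd10 = "I50.9", vw_length_of_stay = 3,
                     bed_days_saved = 2, stringsAsFactors = FALSE)
  expect_error(vw_cohort(base), "step-up")
  base$bed_days_saved <- -1
  base$pathway <- "step_down"
  expect_error(vw_cohort(base), ">= 0")
  ok <- base
  ok$bed_days_saved <- 0
  expect_error(vw_cohort(ok, data.frame(id = "A", kind = "teleportation",
                                        day = 1)), "unknown event kind")
  expect_error(vw_cohort(ok, data.frame(id = "A", kind = "poc_test",
                                        day = -1)), ">= 0")
  expect_error(vw_cohort(ok, data.frame(id = "B", kind = "poc_test",
                                        day = 1)), "unknown patient")
})

test_that("a zero-stay, zero-event VW episode costs only the shared base", {
  # fixed 308113 + set-up 4685 over 648 annualized patients: share ~ 482
  ep <- patient_episode("P1", "step_up")
  bd <- cost_vw_patient(ep, inputs, n_annual = 648)
  expect_equal(bd$overall, (308113 + 4685) / 648)
  expect_equal(round_half_away(bd$overall), 483)  # 482.71: only shared costs
  expect_equal(bd$home_monitoring + bd$home_setup + bd$poc_testing +
                 bd$home_visits + bd$calls + bd$indirect_total, 0)
})

test_that("VW component costs follow the unit costs and activity rates", {
  ev <- data.frame(
    kind = c("home_visit_routine", "home_visit_rapid", "virtual_call",
             "poc_test", "ed_attendance", "readmission", "nhs111_contact"),
    day = c(1, 2, 3, 4, 5, 6, 7))
  ep <- patient_episode("P1", "step_down", vw_length_of_stay = 5,
                        bed_days_saved = 3, events = ev)
  bd <- cost_vw_patient(ep, inputs, n_annual = 648)
  expect_equal(bd$excess_bed_day_savings, -3 * 338)
  expect_equal(bd$home_visits, 2 * 45 * 1.02)
  expect_equal(bd$calls, 10 * 1.79)
  expect_equal(bd$poc_testing, unit_amount(inputs, "poc_test"))
  expect_equal(bd$ed_visits, 158)
  expect_equal(bd$readmission, 2587)
  expect_equal(bd$nhs111, 11)
  expect_equal(bd$home_monitoring, 34)
  expect_equal(bd$home_setup, 30)
  expect_equal(bd$outpatient, 0)          # VW-arm convention
  expect_equal(bd$initial_admission, 0)

  # reference-cost alternative for home visits
  alt <- inputs
  alt$visit_costing <- "reference"
  expect_equal(cost_vw_patient(ep, alt, n_annual = 648)$home_visits, 2 * 102)
})

test_that("SC counterfactual costing follows the published conventions", {
  up <- patient_episode("P1", "step_up")
  bd <- cost_sc_patient(up, inputs)
  expect_equal(bd$initial_admission, 2587)
  expect_equal(bd$overall, 2587)
  expect_equal(bd$direct_total, 0)

  down <- patient_episode("P2", "step_down")
  expect_equal(cost_sc_patient(down, inputs)$overall, 0)

  readmitted <- patient_episode("P3", "step_down",
                                events = data.frame(kind = "readmission",
                                                    day = 10))
  bd <- cost_sc_patient(readmitted, inputs)
  expect_equal(bd$readmission, 2587)
  expect_equal(bd$excess_bed_day_savings, 0)

  op <- patient_episode("P4", "step_down",
                        events = data.frame(kind = "outpatient_appointment",
                                            day = c(2, 9)))
  expect_equal(cost_sc_patient(op, inputs)$outpatient, 2 * 213)
})

test_that("costing is additive over events and totals are exact", {
  co <- apply_horizon(random_cohort(n = 40, seed = 21), 30)
  for (arm in c("vw", "sc")) {
    bd <- cost_cohort(co, inputs, arm, n_annual = 648)
    expect_equal(bd$overall, bd$direct_total + bd$indirect_total)
    expect_equal(bd$overall,
                 rowSums(bd[, c(DIRECT_COMPONENTS, INDIRECT_COMPONENTS)]))
  }
  # single-event episodes sum to the full episode (minus the repeated base)
  p <- co$patients[3, ]
  ev <- co$events[co$events$id == p$id, , drop = FALSE]
  full <- cost_cohort(vw_cohort(p, ev), inputs, "vw", n_annual = 648)$overall
  base <- cost_cohort(vw_cohort(p), inputs, "vw", n_annual = 648)$overall
  singles <- vapply(seq_len(nrow(ev)), function(i) {
    cost_cohort(vw_cohort(p, ev[i, ]), inputs, "vw", n_annual = 648)$overall
  }, numeric(1))
  expect_equal(full, base + sum(singles - base))
})
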