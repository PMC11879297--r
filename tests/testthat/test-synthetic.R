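inputs <- default_config()

test_that("calibrate_rates back-derives implied rates from component costs", {
  # readmission components at the 2587 admission cost
  expect_equal(round(calibrate_rates(c(r = 326), c(r = 2587))[["r"]], 3), 0.126)
  expect_equal(round(calibrate_rates(c(r = 556), c(r = 2587))[["r"]], 3), 0.215)
  # bed-day savings component at the 338/day excess bed day cost
  expect_equal(round(calibrate_rates(c(b = 558), c(b = 338))[["b"]], 3), 1.651)
  expect_error(calibrate_rates(c(a = 10), c(a = 0)), "> 0")
  expect_error(calibrate_rates(c(a = 10), c(b = 1)), "a")
})

test_that("the shipped rates are the Table-5 calibration", {
  cc <- inputs$cohort
  expect_equal(cc$vw_rates$readmission_probability, 326 / 2587)
  expect_equal(cc$sc_rates$readmission_probability, 556 / 2587)
  expect_equal(cc$vw_rates$home_visits, 154 / (45 * 1.02))
  expect_equal(cc$vw_rates$calls, 140 / (10 * 1.79))
  expect_equal(cc$sc_rates$outpatient_appointments, 117 / 213)
  expect_equal(cc$step_up_proportion, 1164 / 2587)
  expect_equal(cc$bed_days_saved_step_down,
               (558 / 338) / (1 - 1164 / 2587))
})

test_that("generation is reproducible and honours the pathway invariant", {
  a <- generate_cohort(inputs, seed = 7)
  b <- generate_cohort(inputs, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(inputs, seed = 8)
  expect_false(identical(a$vw$patients, c$vw$patients))

  all_up <- inputs
  all_up$cohort$step_up_proportion <- 1.0
  g <- generate_cohort(all_up, seed = 3)
  expect_true(all(g$vw$patients$pathway == "step_up"))
  expect_true(all(g$vw$patients$bed_days_saved == 0))
  expect_error(generate_cohort(inputs), "seed")
})

test_that("generated event days exercise the horizon filter", {
  g <- generate_cohort(inputs, seed = 11)
  expect_gt(sum(g$vw$events$day > 30), 0)
  expect_lte(max(g$vw$events$day), inputs$cohort$event_day_max)
  filtered <- apply_horizon(g$vw, 30)
  expect_lt(nrow(filtered$events), nrow(g$vw$events))
})

test_that("within-horizon event rates recover the configured rates (n = 10 000)", {
  big <- inputs
  big$cohort$n_patients <- 10000L
  big$cohort$control_multiplier <- 1   # controls not under test here
  g <- generate_cohort(big, seed = 123)
  vw <- apply_horizon(g$vw, 30)
  n <- nrow(vw$patients)
  counts <- table(factor(vw$events$kind, levels = EVENT_KINDS))

  check_rate <- function(observed_total, rate, binary = FALSE) {
    mean_obs <- observed_total / n
    # Monte-Carlo SE of the mean count (Poisson) or proportion (binomial)
    se <- if (binary) sqrt(rate * (1 - rate) / n) else sqrt(rate / n)
    expect_lt(abs(mean_obs - rate), 3 * se)
  }
  cc <- big$cohort
  check_rate(counts[["home_visit_routine"]] + counts[["home_visit_rapid"]],
             cc$vw_rates$home_visits)
  check_rate(counts[["virtual_call"]], cc$vw_rates$calls)
  check_rate(counts[["poc_test"]], cc$vw_rates$poc_tests)
  check_rate(counts[["nhs111_contact"]], cc$vw_rates$nhs111_contacts)
  check_rate(counts[["ed_attendance"]], cc$vw_rates$ed_probability,
             binary = TRUE)
  check_rate(counts[["readmission"]], cc$vw_rates$readmission_probability,
             binary = TRUE)
  # covariates and pathway mix
  expect_lt(abs(mean(vw$patients$pathway == "step_up") -
                  cc$step_up_proportion), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(vw$patients$age) - cc$age$mean), 1)
  sd_count <- vw$patients$pathway == "step_down"
  expect_lt(abs(mean(vw$patients$bed_days_saved[sd_count]) -
                  cc$bed_days_saved_step_down),
            3 * sqrt(cc$bed_days_saved_step_down / sum(sd_count)))
})

test_that("pipeline closure: accounting identities hold for any seed", {
  for (seed in c(1, 99, 4242)) {
    small <- inputs
    small$cohort$n_patients <- 80L
    g <- generate_cohort(small, seed = seed)
    ps <- estimate_propensity(g$vw$patients, g$controls$patients)
    mr <- match_1to1(ps$treated_scores, ps$control_scores)
    sc <- build_sc_arm(mr, g$vw, g$controls)
    vw_f <- apply_horizon(g$vw, 30)
    sc_f <- apply_horizon(sc, 30)
    ann <- annualize(vw_f, small$cohort$observed_months)
    bd_vw <- cost_cohort(vw_f, small, "vw", n_annual = ann$n_annual)
    bd_sc <- cost_cohort(sc_f, small, "sc")
    expect_equal(bd_vw$overall, bd_vw$direct_total + bd_vw$indirect_total)
    s_vw <- summarize_arm(bd_vw, small, "vw", scale = ann$factor)
    s_sc <- summarize_arm(bd_sc, small, "sc", scale = ann$factor)
    expect_equal(s_vw$population_total,
                 s_vw$setup_total + s_vw$fixed_total + s_vw$variable_total)
    inc <- incremental(s_vw, s_sc)
    expect_equal(inc$incremental_per_patient,
                 inc$incremental_population / s_vw$cohort_size)
    # the SC arm inherits the treated pathway mix, so step-up counterfactuals
    # carry the initial admission
    expect_equal(sum(bd_sc$initial_admission > 0),
                 sum(sc_f$patients$pathway == "step_up"))
  }
})
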