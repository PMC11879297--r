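test_that("with identically distributed pools the mean score is the treated share", {
  pools <- random_pools(n_t = 60, n_c = 120, age_shift = 0, seed = 8)
  ps <- estimate_propensity(pools$treated, pools$controls)
  all_scores <- c(ps$treated_scores, ps$control_scores)
  # logistic MLE with an intercept: mean fitted probability equals prevalence
  expect_equal(mean(all_scores), 60 / 180, tolerance = 1e-8)
  expect_true(all(all_scores > 0 & all_scores < 1))
})

test_that("perfect separation on a covariate is rejected with advice", {
  pools <- random_pools(seed = 2)
  pools$treated$age <- runif(nrow(pools$treated), 80, 95)
  pools$controls$age <- runif(nrow(pools$controls), 40, 60)
  expect_error(suppressWarnings(estimate_propensity(pools$treated,
                                                    pools$controls)),
               "exact matching")
})

test_that("propensity scores match an independently coded Newton fit", {
  pools <- random_pools(n_t = 8, n_c = 12, seed = 31)  # 20-subject pool
  ps <- estimate_propensity(pools$treated, pools$controls)
  pooled <- rbind(cbind(pools$treated, group = 1), cbind(pools$controls, group = 0))
  X <- stats::model.matrix(~ age + factor(gender) + factor(icd10), pooled)
  oracle <- oracle_logistic_fit(X, pooled$group)
  expect_equal(unname(c(ps$treated_scores, ps$control_scores)),
               unname(oracle), tolerance = 1e-6)
})

test_that("identical pools match every treated subject at distance zero", {
  pools <- random_pools(n_t = 15, n_c = 15, age_shift = 0, seed = 4)
  pools$controls[, c("age", "gender", "icd10")] <-
    pools$treated[, c("age", "gender", "icd10")]
  ps <- estimate_propensity(pools$treated, pools$controls)
  mr <- match_1to1(ps$treated_scores, ps$control_scores)
  expect_equal(nrow(mr$pairs), 15)
  expect_equal(length(mr$unmatched_treated), 0)
  expect_equal(max(mr$pairs$distance), 0)
})

test_that("greedy matching equals the enumeration oracle on small pools", {
  t_scores <- c(T1 = 0.30, T2 = 0.82, T3 = 0.55)
  c_scores <- c(C1 = 0.50, C2 = 0.31, C3 = 0.80)
  mr <- match_1to1(t_scores, c_scores)
  oracle <- oracle_greedy_match(t_scores, c_scores)
  expect_equal(mr$pairs$treated_id, oracle$treated)
  expect_equal(mr$pairs$control_id, oracle$control)

  set.seed(99)
  for (i in 1:50) {
    nt <- sample(2:4, 1)
    nc <- sample(2:4, 1)
    ts <- setNames(runif(nt), paste0("T", seq_len(nt)))
    cs <- setNames(runif(nc), paste0("C", seq_len(nc)))
    cal <- if (runif(1) < 0.5) runif(1, 0, 0.3) else NULL
    mr <- match_1to1(ts, cs, caliper = cal)
    oracle <- oracle_greedy_match(ts, cs, caliper = cal)
    expect_equal(mr$pairs$treated_id, oracle$treated)
    expect_equal(mr$pairs$control_id, oracle$control)
  }
})

test_that("matching without replacement never reuses a control", {
  pools <- random_pools(n_t = 50, n_c = 60, seed = 17)
  ps <- estimate_propensity(pools$treated, pools$controls)
  mr <- match_1to1(ps$treated_scores, ps$control_scores)
  expect_false(any(duplicated(mr$pairs$control_id)))
  expect_lte(nrow(mr$pairs), 50)
})

test_that("a zero caliper with all-distinct scores matches nothing", {
  mr <- match_1to1(c(T1 = 0.2, T2 = 0.6), c(C1 = 0.3, C2 = 0.7), caliper = 0)
  expect_equal(nrow(mr$pairs), 0)
  expect_setequal(mr$unmatched_treated, c("T1", "T2"))
  expect_error(match_1to1(c(T1 = 0.5), numeric(0)), "empty")
})

test_that("matching is deterministic and improves age balance in most pools", {
  worse <- 0
  for (s in 1:100) {
    # pools large enough that the pre-match age imbalance is real signal, so
    # regressions can only come from sampling noise (allowed at <= 5%)
    pools <- random_pools(n_t = 50, n_c = 200, age_shift = 4, seed = 1000 + s)
    ps <- estimate_propensity(pools$treated, pools$controls)
    mr <- match_1to1(ps$treated_scores, ps$control_scores,
                     treated = pools$treated, controls = pools$controls)
    again <- match_1to1(ps$treated_scores, ps$control_scores,
                        treated = pools$treated, controls = pools$controls)
    expect_identical(mr$pairs, again$pairs)
    age <- mr$balance[mr$balance$covariate == "age", ]
    if (abs(age$smd_after) > abs(age$smd_before) + 1e-12) worse <- worse + 1
  }
  # sampling noise may flip a few pools, but no more than 5%
  expect_lte(worse, 5)
})
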