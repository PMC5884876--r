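# Closed-loop protocol controller: warm-up, first increment, fine adaptation,
# overshoot handling, verification and whole-session behaviour.

noiseless <- measurement_model(cv = 0)

test_that("warm-up settles at the HR-implied workload and rejects degenerate targets", {
  # target 170 - 30 = 140, inversion (140-60)/25 = 3.2
  s <- test_subject(hr_gain = 25)
  wu <- with_seed(1, run_warmup(s, protocol_config("running"), noiseless))
  expect_equal(wu$workload, 3.2, tolerance = 0.05)
  expect_lt(abs(wu$hr - 140), 2)

  # closed-form inversion within one quantum across varied HR parameters
  set.seed(8)
  for (i in 1:5) {
    su <- test_subject(hr_rest = runif(1, 58, 70), hr_gain = runif(1, 22, 30))
    wu <- run_warmup(su, protocol_config("running"), noiseless)
    expect_lt(abs(wu$workload - (140 - su$hr_rest) / su$hr_gain), 0.05 + 0.026)
  }

  old <- test_subject(age = 170)
  expect_error(run_warmup(old, protocol_config("running"), noiseless),
               class = "iltk_domain_error")
})

test_that("threshold adaptation applies the configured mapping with a quantum floor", {
  cfg <- protocol_config("running", ta_slope = 0, ta_intercept = 0.4)
  expect_equal(threshold_adaptation(3.0, 2.0, cfg), 3.4)

  # increment floor: first workload always above the warm-up workload
  cfg0 <- protocol_config("running", ta_slope = 0, ta_intercept = -1)
  expect_equal(threshold_adaptation(3.0, 2.0, cfg0), 3.05)

  # default mapping lands below the true MLSS for >= 80% of a default cohort
  co <- make_cohort(60, "running", seed = 31)
  cfg <- protocol_config("running")
  below <- vapply(co, function(su) {
    wu <- run_warmup(su, cfg, noiseless)
    threshold_adaptation(wu$workload, wu$lactate, cfg) < su$mlss_workload
  }, logical(1))
  expect_gte(mean(below), 0.8)
})

test_that("fine adaptation band table on the previous step's delta", {
  cfg <- protocol_config("running")
  hist <- function(d) series(c(2.5, 2.5 + d), workload = c(3.4, 3.55))
  expect_equal(next_workload_fta(hist(0.1), cfg),
               list(action = "increase", increment = 0.15, delta = 0.1))
  expect_equal(next_workload_fta(hist(0.3), cfg)$increment, 0.1)
  expect_equal(next_workload_fta(hist(0), cfg)$increment, 0.15)
  expect_identical(next_workload_fta(hist(0.45), cfg)$action, "hold")
  # inclusive band edges
  expect_equal(next_workload_fta(hist(0.2), cfg)$increment, 0.1)
  expect_equal(next_workload_fta(hist(0.4), cfg)$increment, 0.1)
})

test_that("overshoot at the first adapted workload is corrected and the session completes", {
  cfg <- protocol_config("running", ta_slope = 0, ta_intercept = 0.95)
  s <- test_subject(rate = 10, hr_gain = 25)  # warm-up 3.2, first workload 4.15
  ses <- run_ilt_test(s, cfg, seed = 1, model = noiseless)
  expect_identical(ses$outcome, "corrected_overshoot")
  expect_identical(ses$threshold$criterion, "TC2")
  expect_true("overshoot_correction" %in% ses$steps$decision)
  expect_equal(ses$mlss_workload_estimate, 3.95)
  expect_lt(abs(ses$mlss_workload_estimate - s$mlss_workload), 0.1 + 1e-9)

  # delta below the cutoff: no correction on a normal session
  ses2 <- run_ilt_test(test_subject(), protocol_config("running"),
                       seed = 1, model = noiseless)
  expect_false("overshoot_correction" %in% ses2$steps$decision)
  expect_identical(ses2$outcome, "completed")

  # a second consecutive overshoot invalidates the session
  cfg_far <- protocol_config("running", ta_slope = 0, ta_intercept = 1.3)
  ses3 <- run_ilt_test(test_subject(rate = 16, hr_gain = 25), cfg_far, seed = 1,
                       model = noiseless)
  expect_identical(ses3$outcome, "invalid")
  expect_true(is.na(ses3$mlss_workload_estimate))
})

test_that("verification reduces once or twice and sets the estimate accordingly", {
  cfg <- protocol_config("running")
  # staircase crosses MLSS 4.0 by a full big increment (4.15): the first
  # reduction (4.05) is still supra-threshold and fails, the second passes
  s <- test_subject(rate = 12, hr_gain = 25)
  ses <- run_ilt_test(s, cfg, seed = 1, model = noiseless)
  expect_identical(ses$outcome, "completed")
  expect_equal(ses$verification_attempts, 2L)
  expect_equal(ses$mlss_workload_estimate,
               ses$threshold$lt_workload - 2 * cfg$verification_reduction)

  # crossing by one quantum only: first reduction suffices
  s2 <- test_subject(mlss = 3.9, rate = 12)
  ses2 <- run_ilt_test(s2, cfg, seed = 1, model = noiseless)
  expect_identical(ses2$outcome, "completed")
  expect_equal(ses2$verification_attempts, 1L)
  expect_equal(ses2$mlss_workload_estimate,
               ses2$threshold$lt_workload - cfg$verification_reduction)
})

test_that("noiseless lag-0 recovery brackets the true MLSS from below", {
  cfg <- protocol_config("running")
  for (mlss in c(3.1, 3.65, 4.0, 4.45, 4.8)) {
    s <- test_subject(mlss = mlss)
    ses <- run_ilt_test(s, cfg, seed = 1, model = noiseless)
    expect_identical(ses$outcome, "completed")
    expect_gt(ses$mlss_workload_estimate, mlss - 0.1 - 1e-9)
    expect_lte(ses$mlss_workload_estimate, mlss + 1e-9)
  }
})

test_that("a lagged subject produces a delayed criterion after constant-workload steps", {
  s <- test_subject(lag = 3L, rate = 12)
  ses <- run_ilt_test(s, protocol_config("running"), seed = 2,
                      model = noiseless)
  expect_identical(ses$outcome, "completed")
  expect_true(ses$threshold$criterion %in% c("TC1", "TC2"))
  expect_lt(abs(ses$mlss_workload_estimate - s$mlss_workload), 0.15 + 1e-9)
  # session length differs from the lag-0 twin: test duration is variable
  ses0 <- run_ilt_test(test_subject(lag = 0L, rate = 12),
                       protocol_config("running"), seed = 2, model = noiseless)
  expect_false(nrow(ses$steps) == nrow(ses0$steps) &&
                 identical(ses$steps$workload, ses0$steps$workload))
})

test_that("sessions are deterministic under seed and respect workload quantization", {
  s <- test_subject(lag = 2L)
  a <- run_ilt_test(s, protocol_config("running"), seed = 42)
  b <- run_ilt_test(s, protocol_config("running"), seed = 42)
  expect_identical(a, b)
  c <- run_ilt_test(s, protocol_config("running"), seed = 43)
  expect_false(identical(a$steps$lactate, c$steps$lactate))

  w <- a$steps$workload
  expect_true(all(abs(w / 0.05 - round(w / 0.05)) < 1e-6))
  # never more than one big increment per step during fine adaptation
  fa <- which(a$steps$phase == "fine_adaptation")
  dw <- diff(a$steps$workload)[fa - 1]
  expect_true(all(dw <= 0.15 + 1e-9))
})

test_that("max_steps exhaustion yields an invalid session", {
  cfg <- protocol_config("running", max_steps = 6, ta_slope = 0,
                         ta_intercept = 0.05, increment_big = 0.05,
                         increment_small = 0.05)
  ses <- run_ilt_test(test_subject(), cfg, seed = 1, model = noiseless)
  expect_identical(ses$outcome, "invalid")
  expect_identical(ses$threshold$criterion, "none")
  expect_true(is.na(ses$mlss_workload_estimate))
})

test_that("cycling sessions recover the MLSS power analogously", {
  s <- subject_profile("C1", 35, "cycling", mlss_workload = 250,
                       baseline_lactate = 1.2, sub_threshold_gain = 0.0075,
                       supra_threshold_rate = 0.12,
                       lactate_time_constant = 2, accumulation_lag_steps = 0L,
                       hr_rest = 60, hr_gain = (170 - 60) / 250,
                       hr_time_constant = 1, rpe_at_mlss = 5)
  ses <- run_ilt_test(s, protocol_config("cycling"), seed = 1,
                      model = noiseless)
  expect_identical(ses$outcome, "completed")
  expect_lt(abs(ses$mlss_workload_estimate - 250), 10 + 1e-9)
})
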