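# Virtual-subject dynamics: relaxation, supra-threshold accumulation,
# analyzer noise, RPE mapping, cohort generation.

test_that("lactate relaxes to baseline at rest and matches the RK4 oracle below threshold", {
  s <- test_subject()
  st <- physio_state(s)
  st$current_true_lactate <- 4.5
  for (i in 1:100) st <- advance_step(s, st, 0, s$lactate_time_constant)
  expect_equal(st$current_true_lactate, s$baseline_lactate, tolerance = 1e-6)

  # closed-form step vs independent numerical integration, random draws
  set.seed(42)
  for (i in 1:8) {
    su <- test_subject(mlss = runif(1, 3, 4.8), gain = runif(1, 0.3, 0.375),
                       baseline = runif(1, 1.0, 1.4), tau = runif(1, 1.5, 2.5))
    w <- runif(1, 0, su$mlss_workload)
    la0 <- runif(1, 0.8, 4)
    st <- physio_state(su)
    st$current_true_lactate <- la0
    st2 <- advance_step(su, st, w, 4)
    expect_equal(st2$current_true_lactate, rk4_lactate(su, la0, w, 4),
                 tolerance = 1e-4)
  }
})

test_that("sub-threshold workloads reach a steady state", {
  s <- test_subject()
  for (w in c(2.0, 3.5, s$mlss_workload)) {
    st <- physio_state(s)
    deltas <- numeric(10)
    for (i in 1:10) {
      prev <- st$current_true_lactate
      st <- advance_step(s, st, w, 4)
      deltas[i] <- st$current_true_lactate - prev
    }
    expect_lt(abs(deltas[10]), 0.05)
    expect_equal(st$current_true_lactate, steady_state_lactate(s, w),
                 tolerance = 0.05)
  }
})

test_that("supra-threshold lactate rises per step with no steady state, scaling with overshoot", {
  # per-step rise tuned to 1.2 mM at +0.2 m/s: rate = 6
  s <- test_subject(rate = 6)
  st <- physio_state(s)
  la <- numeric(8)
  for (i in 1:8) {
    st <- advance_step(s, st, 4.2, 4)
    la[i] <- st$current_true_lactate
  }
  rises <- diff(la)
  expect_true(all(rises > 0))
  expect_equal(unname(rises[4:7]), rep(1.2, 4), tolerance = 0.05)

  # larger overshoot, larger per-step rise
  rise_at <- function(over) {
    st <- physio_state(s)
    for (i in 1:4) st <- advance_step(s, st, s$mlss_workload + over, 4)
    prev <- st$current_true_lactate
    st <- advance_step(s, st, s$mlss_workload + over, 4)
    st$current_true_lactate - prev
  }
  r <- vapply(c(0.05, 0.1, 0.2, 0.3), rise_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("accumulation lag attenuates the rise until it expires and resets on workload change", {
  s <- test_subject(lag = 3L)
  st <- physio_state(s)
  st <- advance_step(s, st, 3.0, 4)        # sub-threshold
  rises <- numeric(6)
  for (i in 1:6) {
    prev <- st$current_true_lactate
    st <- advance_step(s, st, 4.2, 4)
    rises[i] <- st$current_true_lactate - prev
  }
  full <- s$supra_threshold_rate * 0.2
  expect_equal(rises[2:3], rep(full * s$lag_attenuation, 2), tolerance = 1e-9)
  expect_equal(rises[4:6], rep(full, 3), tolerance = 1e-9)

  # changing workload resets the counter
  expect_equal(st$steps_at_constant_supra_workload, 6L)
  st <- advance_step(s, st, 4.3, 4)
  expect_equal(st$steps_at_constant_supra_workload, 1L)
  st <- advance_step(s, st, 3.0, 4)
  expect_equal(st$steps_at_constant_supra_workload, 0L)
})

test_that("advance_step rejects invalid inputs", {
  s <- test_subject()
  st <- physio_state(s)
  expect_error(advance_step(s, st, 3, -1), class = "iltk_domain_error")
  expect_error(advance_step(s, st, -0.1, 4), class = "iltk_domain_error")
})

test_that("measure_lactate: exact when noise disabled, calibrated CV, seed-reproducible", {
  expect_identical(measure_lactate(3.0, measurement_model(cv = 0)), 3.0)

  m <- measurement_model(cv = 0.03)
  draws <- with_seed(1, measure_lactate(rep(3.0, 1e5), m))
  expect_equal(sd(draws), 0.09, tolerance = 0.02)
  # empirical CV within 5% relative of the configured cv
  expect_lt(abs(sd(draws) / mean(draws) - 0.03), 0.05 * 0.03)

  a <- with_seed(7, measure_lactate(2.5, m))
  b <- with_seed(7, measure_lactate(2.5, m))
  expect_identical(a, b)
  expect_error(measure_lactate(-1, m), class = "iltk_domain_error")
})

test_that("rpe_response is monotone, anchored at MLSS, saturates at 10", {
  s <- test_subject()
  expect_equal(rpe_response(s, 0), 0)
  expect_equal(rpe_response(s, s$mlss_workload), 5)
  expect_equal(rpe_response(s, 2 * s$mlss_workload), 10)
  w <- seq(0, 10, by = 0.25)
  expect_true(all(diff(rpe_response(s, w)) >= 0))
})

test_that("make_cohort: determinism, invariants, degenerate and impossible ranges", {
  c1 <- make_cohort(50, "running", seed = 3)
  c2 <- make_cohort(50, "running", seed = 3)
  expect_identical(c1, c2)

  # every implied threshold-range lactate within the observed window
  ss <- vapply(c1, function(s) steady_state_lactate(s, s$mlss_workload),
               numeric(1))
  expect_true(all(ss >= 1.9 - 1e-9 & ss <= 5 + 1e-9))
  mlss <- vapply(c1, `[[`, numeric(1), "mlss_workload")
  expect_true(all(mlss >= 3.0 - 1e-9 & mlss <= 4.8 + 1e-9))
  expect_true(all(abs(mlss / 0.05 - round(mlss / 0.05)) < 1e-6))
  lag <- vapply(c1, `[[`, integer(1), "accumulation_lag_steps")
  expect_true(all(lag >= 0L & lag <= 7L))

  # degenerate point ranges reproduce the exact subject
  rng <- default_parameter_ranges("running")
  point <- lapply(rng, function(x) rep(mean(x), 2))
  point$mlss_workload <- c(4.0, 4.0)
  one <- make_cohort(1, "running", point, seed = 9)[[1]]
  expect_equal(one$mlss_workload, 4.0)
  expect_equal(one$baseline_lactate, mean(rng$baseline_lactate))

  # impossible ranges rejected
  bad <- default_parameter_ranges("running")
  bad$sub_threshold_gain <- c(0.05, 0.05)   # implied lactate at MLSS < 1.9
  expect_error(make_cohort(5, "running", bad), class = "iltk_domain_error")
  expect_error(make_cohort(0, "running"), class = "iltk_domain_error")
})

test_that("cohort CSV round-trips", {
  co <- make_cohort(5, "cycling", seed = 4)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(length(back), 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$mlss_workload, co[[i]]$mlss_workload)
    expect_equal(back[[i]]$supra_threshold_rate, co[[i]]$supra_threshold_rate)
    expect_identical(back[[i]]$modality, "cycling")
  }
})
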