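# Independent reference implementations ("oracles") and fixture builders used
# across the suite. The oracle code deliberately shares nothing with the
# package internals: plain loops over explicitly enumerated windows.

# Brute-force reference classifier. Scans constant-workload stretches with
# naive loops and applies, per stretch: the steep-rise criterion at the first
# step after an increment (> 0.5 mM vs the previous step), the delayed
# criterion over up to 8 following steps (> 0.4 mM cumulative vs the stretch's
# first step), and the slow-creep criterion (>= 3 consecutive rises > 0.1 mM
# summing to <= 0.5 mM, only if the delayed criterion never fires in the
# stretch). Deltas rounded to 0.01 mM; strict comparisons.
oracle_classify <- function(workload, lactate) {
  n <- length(workload)
  r2 <- function(x) round(x, 2)
  gt <- function(a, b) a > b + 1e-9
  bounds <- list()
  a <- 1
  for (i in seq_len(n)) {
    if (i > 1 && abs(workload[i] - workload[i - 1]) > 1e-9) {
      bounds[[length(bounds) + 1]] <- c(a, i - 1)
      a <- i
    }
  }
  bounds[[length(bounds) + 1]] <- c(a, n)
  for (win in bounds) {
    a <- win[1]; b <- win[2]
    if (a > 1 && gt(workload[a], workload[a - 1])) {
      d <- r2(lactate[a] - lactate[a - 1])
      if (gt(d, 0.5))
        return(list(criterion = "TC1", trigger = a, delta = d))
    }
    fired2 <- NULL
    for (k in 1:8) {
      if (a + k > b) break
      d <- r2(lactate[a + k] - lactate[a])
      if (gt(d, 0.4)) { fired2 <- list(criterion = "TC2", trigger = a + k, delta = d); break }
    }
    if (!is.null(fired2)) return(fired2)
    if (b - a >= 3) {
      run <- 0; rsum <- 0
      for (m in (a + 1):b) {
        d <- r2(lactate[m] - lactate[m - 1])
        if (gt(d, 0.1)) {
          run <- run + 1; rsum <- r2(rsum + d)
          if (run >= 3 && !gt(rsum, 0.5))
            return(list(criterion = "TC2a", trigger = m, delta = rsum))
        } else { run <- 0; rsum <- 0 }
      }
    }
  }
  list(criterion = "none", trigger = NA_integer_, delta = NA_real_)
}

# Classical 4th-order Runge-Kutta integration of the sub-threshold lactate
# ODE dLa/dt = (target - La) / tau; independent check of the closed-form
# exponential step used by the simulator.
rk4_lactate <- function(subject, la0, workload, duration, dt = 0.001) {
  target <- subject$baseline_lactate +
    subject$sub_threshold_gain * max(0, workload)
  f <- function(la) (target - la) / subject$lactate_time_constant
  la <- la0
  for (i in seq_len(round(duration / dt))) {
    k1 <- f(la); k2 <- f(la + dt / 2 * k1)
    k3 <- f(la + dt / 2 * k2); k4 <- f(la + dt * k3)
    la <- la + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  la
}

# Canonical deterministic test subject: MLSS 4.0 m/s, warm-up inversion
# target (140 - 60)/25 = 3.2 m/s.
test_subject <- function(id = "T", mlss = 4.0, lag = 0L, rate = 12,
                         gain = 0.35, baseline = 1.2, tau = 2, age = 30,
                         modality = "running", hr_rest = 60,
                         hr_gain = (170 - hr_rest) / mlss) {
  subject_profile(id = id, age = age, modality = modality,
                  mlss_workload = mlss, baseline_lactate = baseline,
                  sub_threshold_gain = gain, supra_threshold_rate = rate,
                  lactate_time_constant = tau, accumulation_lag_steps = lag,
                  hr_rest = hr_rest, hr_gain = hr_gain, hr_time_constant = 1,
                  rpe_at_mlss = 5)
}

# Step-series builder for detector tests: one increment at position 2 by
# default, then constant workload.
series <- function(lactate, workload = NULL) {
  n <- length(lactate)
  if (is.null(workload)) workload <- c(3.0, rep(3.1, n - 1))
  data.frame(index = seq_len(n) - 1L, workload = workload,
             measured_lactate = lactate)
}

# Enumerate every lactate series of the given length on a 0.1 mM grid.
grid_series <- function(len, levels) {
  g <- do.call(expand.grid, rep(list(levels), len))
  as.matrix(g)
}
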