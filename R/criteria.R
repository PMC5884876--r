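# Stateless threshold-criterion detectors.
#
# A step series is split into "windows": maximal runs of constant workload.
# A window opened by a workload *increment* is examined with TC1 (steep rise
# > 0.5 mM in the step directly after the increment, relative to the last
# step at the old workload). Within any window, TC2 fires at the first of up
# to eight constant-workload steps whose cumulative rise over the window's
# first step exceeds 0.4 mM, and TC2a fires when at least three consecutive
# steps each rise by more than `rise_epsilon` while the episode's cumulative
# rise never reaches the TC1 magnitude (<= 0.5 mM) and TC2 does not fire in
# that window. All lactate differences are rounded to 0.01 mM before the
# strict comparisons so float noise cannot decide a threshold.
#
# The detectors are pure: same series in, same result out, usable both inside
# the live controller and retrospectively on recorded session logs.

# Accept flexible column naming (live controller vs session CSV vs external
# logs) and return plain vectors for speed.
as_step_series <- function(steps) {
  if (is.null(steps) || NROW(steps) == 0)
    stop_domain("empty step series")
  la <- steps[["measured_lactate"]] %||% steps[["lactate_mM"]] %||%
    steps[["lactate"]]
  w <- steps[["workload"]]
  if (is.null(la) || is.null(w))
    stop_domain("step series needs 'workload' and a lactate column")
  if (any(la < 0)) stop_domain("measured lactate must be >= 0")
  idx <- steps[["index"]] %||% (seq_along(w) - 1L)
  list(index = as.integer(idx), workload = as.numeric(w), lactate = as.numeric(la))
}

# Maximal constant-workload runs: matrix with columns start, end (positions)
# and whether the run was entered by an increment.
constant_runs <- function(w) {
  change <- c(TRUE, abs(diff(w)) > 1e-9)
  start <- which(change)
  end <- c(start[-1] - 1L, length(w))
  incr <- logical(length(start))
  if (length(start) > 1)
    incr[-1] <- w[start[-1]] > w[start[-1] - 1L] + 1e-9
  list(start = start, end = end, increment = incr)
}

tc_result <- function(criterion, s, trigger, reference, delta) {
  structure(list(
    criterion = criterion,
    trigger_step = s$index[trigger],
    reference_step = s$index[reference],
    delta_lactate = delta,
    lt_workload = s$workload[trigger],
    lt_lactate = s$lactate[trigger]
  ), class = "threshold_result")
}

tc_none <- function(applicable = TRUE) {
  structure(list(criterion = "none", trigger_step = NA_integer_,
                 reference_step = NA_integer_, delta_lactate = NA_real_,
                 lt_workload = NA_real_, lt_lactate = NA_real_,
                 applicable = applicable),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$criterion == "none") {
    cat("<threshold_result> no criterion fired\n")
  } else {
    cat(sprintf(
      "<threshold_result> %s at step %d (ref %d): delta %.2f mM, LT workload %.2f, LT lactate %.2f mM\n",
      x$criterion, x$trigger_step, x$reference_step, x$delta_lactate,
      x$lt_workload, x$lt_lactate))
  }
  invisible(x)
}

# per-window scans -----------------------------------------------------------

scan_tc1 <- function(s, runs, j, threshold) {
  if (j == 1 || !runs$increment[j]) return(NULL)
  i <- runs$start[j]
  d <- la_round(s$lactate[i] - s$lactate[i - 1L])
  if (exceeds(d, threshold)) tc_result("TC1", s, i, i - 1L, d) else NULL
}

scan_tc2 <- function(s, runs, j, threshold, window) {
  ref <- runs$start[j]
  kmax <- min(window, runs$end[j] - ref)
  if (kmax < 1) return(NULL)
  for (k in seq_len(kmax)) {
    cum <- la_round(s$lactate[ref + k] - s$lactate[ref])
    if (exceeds(cum, threshold))
      return(tc_result("TC2", s, ref + k, ref, cum))
  }
  NULL
}

scan_tc2a <- function(s, runs, j, rise_epsilon, cap, tc2_threshold, tc2_window) {
  # TC2 takes precedence inside a window: a slow creep that sums past the TC2
  # criterion is a delayed threshold, not a sub-criterion one.
  if (!is.null(scan_tc2(s, runs, j, tc2_threshold, tc2_window))) return(NULL)
  ref <- runs$start[j]
  if (runs$end[j] - ref < 3) return(NULL)
  run_len <- 0L; run_sum <- 0; run_start <- NA_integer_
  for (m in seq.int(ref + 1L, runs$end[j])) {
    d <- la_round(s$lactate[m] - s$lactate[m - 1L])
    if (exceeds(d, rise_epsilon)) {
      if (run_len == 0L) run_start <- m
      run_len <- run_len + 1L
      run_sum <- la_round(run_sum + d)
      if (run_len >= 3L && !exceeds(run_sum, cap))
        return(tc_result("TC2a", s, m, run_start - 1L, run_sum))
    } else {
      run_len <- 0L; run_sum <- 0
    }
  }
  NULL
}

# exported detectors ----------------------------------------------------------

#' Detect the immediate threshold criterion (TC1)
#'
#' Fires when measured lactate in the step directly after a workload increment
#' exceeds the lactate of the last step at the previous workload by strictly
#' more than `threshold` (0.5 mM). The earliest qualifying increment in the
#' series wins.
#'
#' @param steps ordered step series: data frame with columns `workload` and
#'   `measured_lactate` (aliases `lactate`, `lactate_mM` accepted), optionally
#'   `index`.
#' @param threshold mM, default 0.5.
#' @return a `threshold_result`; `criterion` is `"none"` when the criterion
#'   does not fire, with `applicable = FALSE` when the series contains no
#'   workload increment at all.
#' @export
detect_tc1 <- function(steps, threshold = 0.5) {
  s <- as_step_series(steps)
  if (length(s$workload) < 2) stop_domain("need at least 2 steps")
  runs <- constant_runs(s$workload)
  if (!any(runs$increment)) return(tc_none(applicable = FALSE))
  for (j in seq_along(runs$start)) {
    hit <- scan_tc1(s, runs, j, threshold)
    if (!is.null(hit)) return(hit)
  }
  tc_none()
}

#' Detect the delayed threshold criterion (TC2)
#'
#' Within a run of constant workload, fires at the first step `k`
#' (1 <= k <= `window`) whose cumulative lactate rise over the run's first
#' step strictly exceeds `threshold` (0.4 mM); beyond `window` (8) steps the
#' criterion does not fire. The window restarts at every workload change.
#'
#' @inheritParams detect_tc1
#' @param threshold mM, default 0.4.
#' @param window maximum number of constant-workload steps, default 8.
#' @export
detect_tc2 <- function(steps, threshold = 0.4, window = 8) {
  s <- as_step_series(steps)
  if (length(s$workload) < 2) stop_domain("need at least 2 steps")
  runs <- constant_runs(s$workload)
  for (j in seq_along(runs$start)) {
    hit <- scan_tc2(s, runs, j, threshold, window)
    if (!is.null(hit)) return(hit)
  }
  tc_none()
}

#' Detect the slow-creep threshold criterion (TC2a)
#'
#' Fires when at least three consecutive constant-workload steps each rise by
#' strictly more than `rise_epsilon` while the episode's cumulative rise stays
#' at or below `cap` (0.5 mM) and TC2 does not fire in that constant-workload
#' run (TC2 takes precedence).
#'
#' @inheritParams detect_tc2
#' @param rise_epsilon minimal per-step rise counted as "slowly increasing",
#'   default 0.1 mM (the analyzer's resolution scale).
#' @param cap cumulative ceiling, default 0.5 mM.
#' @param tc2_threshold,tc2_window TC2 parameters used for the precedence
#'   check.
#' @export
detect_tc2a <- function(steps, rise_epsilon = 0.1, cap = 0.5,
                        tc2_threshold = 0.4, tc2_window = 8) {
  s <- as_step_series(steps)
  if (length(s$workload) < 2) stop_domain("need at least 2 steps")
  runs <- constant_runs(s$workload)
  for (j in seq_along(runs$start)) {
    hit <- scan_tc2a(s, runs, j, rise_epsilon, cap, tc2_threshold, tc2_window)
    if (!is.null(hit)) return(hit)
  }
  tc_none()
}

#' Classify a step series against all threshold criteria
#'
#' Walks the constant-workload windows in order and, within each window,
#' applies TC1, then TC2, then TC2a; the first window in which any criterion
#' fires determines the result. Pure and idempotent; usable after every live
#' protocol step or retrospectively on a full recorded series.
#'
#' @inheritParams detect_tc1
#' @param tc1_threshold,tc2_threshold,tc2_window,rise_epsilon,tc2a_cap
#'   criterion parameters; defaults are the protocol values.
#' @return a `threshold_result`.
#' @export
classify_steps <- function(steps, tc1_threshold = 0.5, tc2_threshold = 0.4,
                           tc2_window = 8, rise_epsilon = 0.1, tc2a_cap = 0.5) {
  s <- as_step_series(steps)
  runs <- constant_runs(s$workload)
  for (j in seq_along(runs$start)) {
    hit <- scan_tc1(s, runs, j, tc1_threshold)
    if (is.null(hit)) hit <- scan_tc2(s, runs, j, tc2_threshold, tc2_window)
    if (is.null(hit)) hit <- scan_tc2a(s, runs, j, rise_epsilon, tc2a_cap,
                                       tc2_threshold, tc2_window)
    if (!is.null(hit)) return(hit)
  }
  tc_none()
}
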