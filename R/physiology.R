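# Lactate / heart-rate / RPE dynamics of a virtual subject.

#' Advance a subject's physiology through one constant-workload step
#'
#' Below or at the MLSS workload, true lactate relaxes first-order (time
#' constant `lactate_time_constant`) toward the workload-linear steady state
#' [steady_state_lactate()]. Above it, lactate accumulates with no steady
#' state: it relaxes *upward* toward the extrapolated steady-state line if it
#' is still below it, never decays while the workload stays supra-threshold
#' (clearance is saturated), and gains
#' `supra_threshold_rate * (workload - mlss_workload) * duration/4` mM per
#' step. During the first `accumulation_lag_steps` constant-workload steps the
#' gain is attenuated by `lag_attenuation`, producing the slow drift that sums
#' past the delayed threshold criterion one to eight steps after an increment.
#' The step counter resets whenever the workload changes. Heart rate relaxes
#' first-order toward `hr_rest + hr_gain * workload`.
#'
#' @param subject a [subject_profile()].
#' @param state a [physio_state()].
#' @param workload prescribed workload (>= 0), workload units.
#' @param duration step duration in minutes (> 0); the nominal protocol step
#'   is 4 min.
#' @return the new `physio_state`.
#' @export
advance_step <- function(subject, state, workload, duration) {
  if (!is.numeric(duration) || duration <= 0)
    stop_domain("duration must be > 0")
  if (!is.numeric(workload) || workload < 0)
    stop_domain("workload must be >= 0")

  supra <- workload > subject$mlss_workload + 1e-9
  same_w <- !is.na(state$last_workload) &&
    abs(workload - state$last_workload) < 1e-9
  n_supra <- if (supra) {
    if (same_w) state$steps_at_constant_supra_workload + 1L else 1L
  } else 0L

  target <- steady_state_lactate(subject, workload)
  relax <- target + (state$current_true_lactate - target) *
    exp(-duration / subject$lactate_time_constant)
  la <- if (!supra) {
    relax
  } else {
    gate <- if (n_supra <= subject$accumulation_lag_steps)
      subject$lag_attenuation else 1
    max(state$current_true_lactate, relax) +
      subject$supra_threshold_rate * (workload - subject$mlss_workload) *
      (duration / 4) * gate
  }

  hr_target <- subject$hr_rest + subject$hr_gain * workload
  hr <- hr_target + (state$current_hr - hr_target) *
    exp(-duration / subject$hr_time_constant)

  structure(list(
    current_true_lactate = la,
    current_hr = hr,
    steps_at_constant_supra_workload = n_supra,
    last_workload = workload,
    elapsed_time = state$elapsed_time + duration
  ), class = "physio_state")
}

#' Simulate one analyzer reading
#'
#' Returns `true_lactate * (1 + eps)` with `eps ~ N(0, cv)`, truncated at
#' zero. With `cv = 0` the reading equals the true value exactly. Vectorized
#' over `true_lactate`; reproducible under the caller's RNG seed.
#'
#' @param true_lactate true concentration(s), mM (>= 0).
#' @param model a [measurement_model()].
#' @return measured concentration(s), mM.
#' @export
measure_lactate <- function(true_lactate, model = measurement_model()) {
  if (any(true_lactate < 0)) stop_domain("true_lactate must be >= 0")
  if (model$cv == 0) return(true_lactate)
  eps <- stats::rnorm(length(true_lactate), 0, model$cv)
  pmax(0, true_lactate * (1 + eps))
}

#' Rating of perceived exertion at a workload
#'
#' Linear in workload, anchored at `rpe_at_mlss` (default 5 on the modified
#' 0-10 Borg scale: the effort sustainable for 60 min) at the MLSS workload,
#' 0 at rest, saturating at 10.
#'
#' @param subject a [subject_profile()].
#' @param workload workload units (>= 0).
#' @return RPE on 0-10.
#' @export
rpe_response <- function(subject, workload) {
  if (any(workload < 0)) stop_domain("workload must be >= 0")
  pmin(10, subject$rpe_at_mlss * workload / subject$mlss_workload)
}
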